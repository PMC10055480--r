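#' Construct an abundance table
#'
#' A samples-by-taxa table of non-negative sequencing counts, the basic input
#' of all network estimation in this package. Rows are samples, columns are
#' taxa (OTUs or any other taxonomic unit).
#'
#' @param counts numeric matrix (or coercible), samples in rows, taxa in
#'   columns; all entries must be non-negative and finite.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to existing rownames or `sample1..n`.
#' @param taxon_ids character vector of unique taxon identifiers; defaults to
#'   existing colnames or `taxon1..p`.
#' @return An object of class `abundance_table`: the counts matrix with
#'   dimnames set, carrying its identifiers.
#' @export
abundance_table <- function(counts, sample_ids = NULL, taxon_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(counts)
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(counts)))
  }
  if (is.null(taxon_ids)) {
    taxon_ids <- colnames(counts)
    if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(ncol(counts)))
  }
  if (length(sample_ids) != nrow(counts)) stop("sample_ids length mismatch")
  if (length(taxon_ids) != ncol(counts)) stop("taxon_ids length mismatch")
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids")
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon_ids")
  dimnames(counts) <- list(as.character(sample_ids), as.character(taxon_ids))
  structure(counts, class = c("abundance_table", "matrix", "array"))
}

#' @method print abundance_table
#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa\n", nrow(x), ncol(x)))
  cat(sprintf("  total counts: %g; zero fraction: %.3f\n",
              sum(x), mean(x == 0)))
  invisible(x)
}

# Subsetting keeps the class so that leave-one-out subtables remain valid
# inputs to the network estimators.
#' @export
`[.abundance_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("abundance_table", "matrix", "array")
  out
}

#' Convert counts to relative abundances (fractions)
#'
#' Divides each sample's (pseudocount-shifted) counts by its total so each row
#' sums to one. A positive pseudocount makes every fraction strictly positive,
#' which the log-ratio machinery requires when zeros are present.
#'
#' @param table an [abundance_table()] (or bare counts matrix).
#' @param pseudocount value added to every count before normalisation;
#'   must be > 0 if the table contains zeros.
#' @return numeric matrix of fractions, rows summing to 1.
#' @export
to_fractions <- function(table, pseudocount = 0.5) {
  counts <- unclass(as.matrix(table))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(counts == 0)) {
    if (any(rowSums(counts) == 0)) stop("degenerate sample: all-zero row with pseudocount 0")
    if (any(counts == 0)) stop("zero counts present: use a positive pseudocount")
  }
  shifted <- counts + pseudocount
  rs <- rowSums(shifted)
  if (any(rs == 0)) stop("degenerate sample: all-zero row with pseudocount 0")
  sweep(shifted, 1, rs, "/")
}
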