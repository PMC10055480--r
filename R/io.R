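#' Read a counts TSV into an abundance table
#'
#' Expects a header row of taxon IDs and a first column of sample IDs
#' (sample-major). A taxa-major file (taxa in rows) is auto-detected by
#' comparing the first-column entries against the metadata sample IDs when
#' supplied, or by shape heuristics, and transposed with a warning.
#'
#' @param path TSV file.
#' @param sample_ids optional known sample IDs used to orient the table.
#' @return an [abundance_table()].
#' @export
read_counts_tsv <- function(path, sample_ids = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!is.null(sample_ids)) {
    row_overlap <- length(intersect(ids, sample_ids))
    col_overlap <- length(intersect(colnames(m), sample_ids))
    if (col_overlap > row_overlap) {
      warning("counts file appears taxa-major; transposing")
      m <- t(m)
    }
  }
  abundance_table(m)
}

#' Write an abundance table as sample-major TSV
#'
#' @param table an [abundance_table()].
#' @param path output file.
#' @export
write_counts_tsv <- function(table, path) {
  df <- data.frame(sample_id = rownames(table),
                   as.data.frame(unclass(as.matrix(table))),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a metadata TSV (first column = sample ID)
#'
#' @param path TSV file.
#' @return data.frame with sample IDs as rownames.
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample IDs in metadata")
  out <- df[, -1, drop = FALSE]
  rownames(out) <- ids
  out
}

#' Write a metadata data.frame as TSV
#'
#' @param metadata data.frame with sample IDs as rownames.
#' @param path output file.
#' @export
write_metadata_tsv <- function(metadata, path) {
  df <- data.frame(sample_id = rownames(metadata), metadata,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load, align and filter a counts/metadata pair
#'
#' Inner-joins the two tables on sample ID, drops samples with missing group
#' or covariate values (reported, never imputed), and applies a prevalence
#' filter: a taxon is kept iff it is nonzero in at least `prevalence` fraction
#' of the retained samples.
#'
#' @param counts_path counts TSV (see [read_counts_tsv()]).
#' @param metadata_path metadata TSV.
#' @param group_col binary group column name.
#' @param covariate_cols covariate column names checked for missingness.
#' @param prevalence minimum nonzero fraction for a taxon to be kept
#'   (in \[0, 1); 0 keeps all taxa).
#' @param counts_t2_path optional second-time-point counts TSV (paired mode);
#'   aligned to the same samples and taxa.
#' @return list with `table` (+ `table_t2` if requested), `metadata`, and
#'   `report` (samples/taxa dropped and why).
#' @export
load_and_align <- function(counts_path, metadata_path, group_col,
                           covariate_cols = character(0), prevalence = 0,
                           counts_t2_path = NULL) {
  if (prevalence < 0 || prevalence >= 1) stop("prevalence must lie in [0, 1)")
  meta <- read_metadata_tsv(metadata_path)
  table <- read_counts_tsv(counts_path, sample_ids = rownames(meta))
  shared <- intersect(rownames(table), rownames(meta))
  if (!length(shared)) stop("no overlapping samples between counts and metadata")
  dropped_unmatched <- union(setdiff(rownames(table), shared),
                             setdiff(rownames(meta), shared))
  meta <- meta[shared, , drop = FALSE]
  cols <- c(group_col, covariate_cols)
  missing_cols <- setdiff(cols, names(meta))
  if (length(missing_cols)) stop("metadata lacks columns: ",
                                 paste(missing_cols, collapse = ", "))
  incomplete <- rowSums(is.na(meta[, cols, drop = FALSE])) > 0
  dropped_missing <- shared[incomplete]
  keep <- shared[!incomplete]
  table <- table[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  prev <- colMeans(as.matrix(table) > 0)
  keep_taxa <- prev >= prevalence
  dropped_taxa <- colnames(table)[!keep_taxa]
  table <- table[, keep_taxa, drop = FALSE]
  out <- list(table = abundance_table(as.matrix(table)), metadata = meta,
              report = list(dropped_unmatched_samples = dropped_unmatched,
                            dropped_incomplete_samples = dropped_missing,
                            dropped_low_prevalence_taxa = dropped_taxa,
                            n_samples = nrow(table), n_taxa = ncol(table)))
  if (!is.null(counts_t2_path)) {
    t2 <- read_counts_tsv(counts_t2_path, sample_ids = rownames(meta))
    if (!all(keep %in% rownames(t2)))
      stop("second-time-point counts lack samples: ",
           paste(setdiff(keep, rownames(t2)), collapse = ", "))
    t2 <- t2[keep, colnames(out$table), drop = FALSE]
    out$table_t2 <- abundance_table(as.matrix(t2))
  }
  out
}

#' Write a truth specification as JSON (edge lists, spiked sets, eta)
#'
#' @param truth truth list from [simulate_replicate()].
#' @param path output JSON file.
#' @export
write_truth_json <- function(truth, path) {
  edges <- function(a) {
    idx <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
    if (!nrow(idx)) return(matrix(integer(0), 0, 2))
    unname(idx)
  }
  jsonlite::write_json(
    list(edges_group1 = edges(truth$omega1),
         edges_group2 = edges(truth$omega2),
         p = ncol(truth$omega1),
         spiked1 = truth$spiked1, spiked2 = truth$spiked2,
         eta = truth$eta),
    path, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a truth specification written by [write_truth_json()]
#'
#' @param path JSON file.
#' @return list with `omega1`, `omega2`, `spiked1`, `spiked2`, `eta`.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- x$p
  fill <- function(e) {
    a <- matrix(0L, p, p)
    e <- matrix(as.integer(unlist(e)), ncol = 2)
    if (nrow(e)) { a[e] <- 1L; a[e[, 2:1, drop = FALSE]] <- 1L }
    a
  }
  list(omega1 = fill(x$edges_group1), omega2 = fill(x$edges_group2),
       spiked1 = as.integer(x$spiked1), spiked2 = as.integer(x$spiked2),
       eta = as.integer(x$eta))
}
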