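#' Build the pseudo-value regression design matrix
#'
#' Intercept, the binary group indicator coded 0/1 (second sorted level = 1),
#' then covariate columns; categorical covariates are expanded to
#' reference-coded indicator columns with the lexicographically first level
#' as reference.
#'
#' @param metadata data.frame of per-sample variables.
#' @param group_col name of the binary group column.
#' @param covariate_cols character vector of covariate column names.
#' @return list with `X` (design matrix), `group_levels` (sorted levels,
#'   level 2 coded 1) and `z` (the 0/1 group code).
#' @export
build_design <- function(metadata, group_col, covariate_cols = character(0)) {
  if (!group_col %in% names(metadata)) stop("group column not found: ", group_col)
  missing_cols <- setdiff(covariate_cols, names(metadata))
  if (length(missing_cols)) stop("covariate columns not found: ",
                                 paste(missing_cols, collapse = ", "))
  g <- as.character(metadata[[group_col]])
  lev <- sort(unique(g))
  if (length(lev) != 2) stop("group column must have exactly 2 levels, got ",
                             length(lev))
  z <- as.numeric(g == lev[2])
  X <- cbind(`(Intercept)` = 1, Z = z)
  for (cv in covariate_cols) {
    v <- metadata[[cv]]
    if (anyNA(v)) {
      bad <- rownames(metadata)[is.na(v)]
      if (is.null(bad)) bad <- which(is.na(v))
      stop("missing values in covariate '", cv, "' for samples: ",
           paste(bad, collapse = ", "))
    }
    if (is.numeric(v)) {
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- cv
    } else {
      f <- factor(as.character(v))
      levs <- sort(levels(f))
      for (l in levs[-1]) {
        X <- cbind(X, as.numeric(as.character(v) == l))
        colnames(X)[ncol(X)] <- paste0(cv, l)
      }
    }
  }
  list(X = X, group_levels = lev, z = z)
}

#' Differential network analysis via pseudo-value regression (SOHPIE-DNA)
#'
#' The full pipeline: (1) samples are split by the binary group; (2) within
#' each group a SparCC association network is estimated on the full group and
#' on every leave-one-out subset, giving jackknife pseudo-values of each
#' taxon's degree centrality; (3) pseudo-values are stacked across groups and,
#' per taxon, regressed on intercept, group and covariates by least trimmed
#' squares; (4) the group coefficient \eqn{\beta_k} is tested with a Wald t
#' statistic; (5) p-values are converted to q-values across the p taxa; (6)
#' taxa with q-value below `alpha` are flagged as differentially connected
#' (DC).
#'
#' With `table_t2` supplied the statistic becomes the degree centrality of the
#' time-2 minus time-1 difference network (paired temporal mode); samples must
#' then match between the two tables.
#'
#' @param table an [abundance_table()] (time 1 in the paired mode).
#' @param metadata data.frame with one row per sample of `table`, in the same
#'   order (or with rownames matching sample ids).
#' @param group_col name of the binary group column in `metadata`.
#' @param covariate_cols names of adjustment covariates (may be empty).
#' @param alpha FDR level for the DC flag.
#' @param table_t2 optional time-2 table for the paired temporal mode.
#' @param pseudocount,exclusion_threshold,max_exclusion_iters SparCC options,
#'   see [sparcc_correlation()].
#' @param trim_c,lts_nsamp LTS options, see [lts_fit()].
#' @param absolute_degree sum absolute correlations in the degree centrality.
#' @param workers forked workers for the leave-one-out loops.
#' @param seed integer seed controlling the LTS subset search.
#' @return data.frame of class `sohpie_result` with one row per taxon:
#'   `taxon_id`, `beta`, `se`, `t`, `p_value`, `q_value`, `dc` (0/1), plus the
#'   covariate coefficient estimates as attribute `gamma` and the pseudo-value
#'   matrix as attribute `pseudovalues`.
#' @export
sohpie_dna <- function(table, metadata, group_col, covariate_cols = character(0),
                       alpha = 0.05, table_t2 = NULL,
                       pseudocount = 0.5, exclusion_threshold = 0.1,
                       max_exclusion_iters = 10,
                       trim_c = 0.5, lts_nsamp = 50L,
                       absolute_degree = FALSE, workers = 1L, seed = 1L) {
  table <- as.matrix(table)
  n <- nrow(table)
  if (nrow(metadata) != n) stop("metadata rows must match table samples")
  if (!is.null(rownames(metadata)) && !is.null(rownames(table)) &&
      !all(rownames(metadata) == rownames(table))) {
    if (!all(sort(rownames(metadata)) == sort(rownames(table))))
      stop("metadata samples do not match table samples")
    metadata <- metadata[rownames(table), , drop = FALSE]
  }
  des <- build_design(metadata, group_col, covariate_cols)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")

  pv <- grouped_pseudovalues(abundance_table(table), group = des$z,
                             table_t2 = table_t2,
                             absolute_degree = absolute_degree,
                             workers = workers,
                             pseudocount = pseudocount,
                             exclusion_threshold = exclusion_threshold,
                             max_exclusion_iters = max_exclusion_iters)
  p <- ncol(pv)
  taxa <- colnames(pv)
  X <- des$X
  k <- ncol(X)

  beta <- se <- tstat <- pval <- numeric(p)
  gamma <- matrix(NA_real_, p, k - 2,
                  dimnames = list(taxa, colnames(X)[-(1:2)]))
  for (j in seq_len(p)) {
    fit <- lts_fit(pv[, j], X, trim_c = trim_c, nsamp = lts_nsamp,
                   seed = seed + j)
    beta[j] <- fit$coefficients["Z"]
    se[j] <- fit$se["Z"]
    tst <- test_beta(beta[j], se[j], fit$df)
    tstat[j] <- tst$U
    pval[j] <- tst$p_value
    if (k > 2) gamma[j, ] <- fit$coefficients[-(1:2)]
  }
  qval <- qvalues(pval)
  out <- data.frame(taxon_id = taxa, beta = beta, se = se, t = tstat,
                    p_value = pval, q_value = qval,
                    dc = as.integer(qval < alpha), stringsAsFactors = FALSE)
  attr(out, "gamma") <- gamma
  attr(out, "pseudovalues") <- pv
  attr(out, "group_levels") <- des$group_levels
  attr(out, "alpha") <- alpha
  class(out) <- c("sohpie_result", "data.frame")
  out
}

#' @method print sohpie_result
#' @export
print.sohpie_result <- function(x, ...) {
  cat(sprintf("SOHPIE-DNA result: %d taxa, %d differentially connected at q < %g\n",
              nrow(x), sum(x$dc), attr(x, "alpha")))
  top <- x[order(x$q_value), , drop = FALSE]
  print.data.frame(utils::head(top, 10), row.names = FALSE, digits = 4)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Write a per-taxon result table (sorted by q-value) with a JSON sidecar
#'
#' @param result a `sohpie_result`.
#' @param path output TSV path; the configuration sidecar is written next to
#'   it as `<path>.config.json`.
#' @param config optional named list echoed into the sidecar.
#' @export
write_result_tsv <- function(result, path, config = NULL) {
  df <- as.data.frame(result)[order(result$q_value), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- c(list(alpha = attr(result, "alpha"),
                    group_levels = attr(result, "group_levels"),
                    n_taxa = nrow(result), n_dc = sum(result$dc)),
               config)
  jsonlite::write_json(sidecar, paste0(path, ".config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
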