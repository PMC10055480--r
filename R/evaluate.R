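#' Confusion metrics for differential-connectivity calls
#'
#' Scores q-value calls (`q < alpha`) against the true
#' differential-connectivity indicator: precision (fraction of called taxa
#' that are truly DC), recall (fraction of truly DC taxa called), their
#' harmonic mean F1, and accuracy ((TP + TN) / p). Ratios with a zero
#' denominator (no discoveries, no true DC taxa, or precision + recall = 0)
#' are reported as `NA` rather than forced to zero.
#'
#' @param eta 0/1 truth vector.
#' @param q q-values, same length.
#' @param alpha decision threshold on the q-values.
#' @return list with `precision`, `recall`, `f1`, `accuracy`,
#'   `n_discoveries`, `n_true_dc`.
#' @export
confusion_metrics <- function(eta, q, alpha = 0.05) {
  if (length(eta) != length(q)) stop("eta and q must have equal length")
  eta <- as.integer(eta)
  call <- q < alpha
  tp <- sum(eta == 1 & call)
  fp <- sum(eta == 0 & call)
  fn <- sum(eta == 1 & !call)
  tn <- sum(eta == 0 & !call)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  accuracy <- (tp + tn) / length(eta)
  list(precision = precision, recall = recall, f1 = f1, accuracy = accuracy,
       n_discoveries = tp + fp, n_true_dc = tp + fn)
}

#' Run a replicated simulation study over a grid of conditions
#'
#' For each grid row (a simulation condition) this repeats: generate a
#' replicate, run the full differential-network pipeline, and score the calls
#' against the replicate's truth. Metric means are taken over replicates where
#' the metric is defined (undefined 0/0 replicates are excluded, not zeroed).
#' Replicate r of every cell uses seed `seed + r`, recorded in the
#' per-replicate output.
#'
#' @param grid data.frame with columns `p`, `n`, `setting`, and `delta1`,
#'   `delta2` (use `delta2` for the univariable \eqn{\delta}); any further
#'   [sim_config()] fields present as columns override the defaults.
#' @param n_replicates replicates per grid row.
#' @param alpha FDR level for the DC call.
#' @param seed base seed.
#' @param workers forked workers passed to the pipeline.
#' @param verbose print per-cell progress.
#' @param ... further options passed to [sohpie_dna()].
#' @return list with `summary` (one row per grid cell: the grid columns plus
#'   mean precision/recall/f1/accuracy, `n_ok` and `n_failed`) and
#'   `replicates` (per-replicate metric rows with their seeds).
#' @export
run_simulation_study <- function(grid, n_replicates = 30, alpha = 0.05,
                                 seed = 1L, workers = 1L, verbose = FALSE, ...) {
  grid <- as.data.frame(grid)
  need <- c("p", "n", "setting")
  if (!all(need %in% names(grid))) stop("grid needs columns p, n, setting")
  cfg_fields <- setdiff(names(formals(sim_config)), c("delta", "setting"))
  rep_rows <- list()
  summ <- list()
  for (ci in seq_len(nrow(grid))) {
    row <- grid[ci, , drop = FALSE]
    args <- as.list(row[intersect(names(row), cfg_fields)])
    args$setting <- as.character(row$setting)
    cfg <- do.call(sim_config, args)
    mets <- list()
    n_failed <- 0
    for (r in seq_len(n_replicates)) {
      rep_seed <- seed + r
      m <- tryCatch({
        sim <- simulate_replicate(cfg, seed = rep_seed)
        covs <- if (cfg$setting == "multivariable") "X" else character(0)
        res <- sohpie_dna(sim$table, sim$metadata, group_col = "Z",
                          covariate_cols = covs, alpha = alpha,
                          seed = rep_seed, workers = workers, ...)
        cm <- confusion_metrics(sim$truth$eta, res$q_value, alpha)
        cm$seed <- rep_seed
        cm
      }, error = function(e) {
        warning(sprintf("replicate %d of cell %d failed: %s", r, ci,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(m)) { n_failed <- n_failed + 1; next }
      mets[[length(mets) + 1]] <- m
      rep_rows[[length(rep_rows) + 1]] <-
        cbind(row, as.data.frame(m), row.names = NULL)
    }
    mean_def <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    get <- function(f) vapply(mets, function(m) as.numeric(m[[f]]), numeric(1))
    cell <- cbind(row,
                  data.frame(precision = mean_def(get("precision")),
                             recall = mean_def(get("recall")),
                             f1 = mean_def(get("f1")),
                             accuracy = mean_def(get("accuracy")),
                             n_ok = length(mets), n_failed = n_failed),
                  row.names = NULL)
    summ[[ci]] <- cell
    if (verbose) {
      message(sprintf("cell %d/%d (%s p=%d n=%d): recall %.3f precision %.3f f1 %.3f",
                      ci, nrow(grid), cfg$setting, cfg$p, cfg$n,
                      cell$recall, cell$precision, cell$f1))
    }
  }
  list(summary = do.call(rbind, summ),
       replicates = do.call(rbind, rep_rows))
}

#' Write a simulation-study summary as TSV
#'
#' @param study result of [run_simulation_study()].
#' @param path output file for the summary; per-replicate rows are written to
#'   `<path>.replicates.tsv`.
#' @export
write_study_tsv <- function(study, path) {
  utils::write.table(study$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$replicates, paste0(path, ".replicates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
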