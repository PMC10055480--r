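#' Degree centrality of every taxon
#'
#' The per-taxon network summary being tested: the marginal (column) sum of
#' the association matrix, \eqn{\theta_k = \sum_j \rho_{jk}}. The unit
#' diagonal is included in the sum; it adds the same constant to every taxon
#' and so can only shift the regression intercept, never the group effect.
#' With `absolute = TRUE` the summands are \eqn{|\rho_{jk}|} (sensitivity
#' analysis; not the default).
#'
#' @param assoc p x p association matrix.
#' @param absolute sum absolute correlations instead of signed ones.
#' @return named numeric vector of length p.
#' @export
degree_centrality <- function(assoc, absolute = FALSE) {
  m <- unclass(as.matrix(assoc))
  if (absolute) m <- abs(m)
  colSums(m)
}

#' Leave-one-out jackknife pseudo-values of taxon degree centrality
#'
#' For a statistic \eqn{\hat\theta} computed on n samples, the pseudo-value of
#' sample i is \eqn{\tilde\theta_i = n\hat\theta - (n-1)\hat\theta_{(i)}},
#' where \eqn{\hat\theta_{(i)}} is the statistic recomputed without sample i.
#' Pseudo-values act as approximately independent subject-level observations
#' of the statistic and can therefore be regressed on subject covariates.
#'
#' The estimator is invoked exactly `nrow(table) + 1` times (full data plus
#' one per left-out sample); leave-one-out re-estimation is embarrassingly
#' parallel and `workers > 1` uses [parallel::mclapply()] with results
#' identical to the serial path.
#'
#' @param table an [abundance_table()] holding one group's samples.
#' @param estimator function mapping an abundance table to a numeric vector
#'   of per-taxon statistics; defaults to SparCC degree centrality.
#' @param workers number of forked workers for the leave-one-out loop.
#' @return n x p matrix of pseudo-values (rows in input sample order), with
#'   attributes `theta_full` (the full-sample statistic) and `theta_loo`
#'   (n x p matrix of leave-one-out statistics).
#' @export
jackknife_pseudovalues <- function(table, estimator = NULL, workers = 1L) {
  table <- as.matrix(table)
  n <- nrow(table)
  if (n < 5) stop("need at least 5 samples per group for jackknife re-estimation")
  if (is.null(estimator)) {
    estimator <- function(tab) degree_centrality(sparcc_correlation(tab))
  }
  theta_full <- estimator(abundance_table(table))
  p <- length(theta_full)

  loo_one <- function(i) {
    sub <- abundance_table(table[-i, , drop = FALSE])
    res <- tryCatch(estimator(sub), error = function(e)
      stop(sprintf("estimator failed on leave-one-out subtable (sample '%s'): %s",
                   rownames(table)[i], conditionMessage(e)), call. = FALSE))
    as.numeric(res)
  }
  loo <- if (workers > 1L) {
    parallel::mclapply(seq_len(n), loo_one, mc.cores = workers)
  } else {
    lapply(seq_len(n), loo_one)
  }
  theta_loo <- do.call(rbind, loo)
  pv <- matrix(rep(n * theta_full, each = n), n, p) - (n - 1) * theta_loo
  dimnames(pv) <- list(rownames(table), names(theta_full))
  dimnames(theta_loo) <- dimnames(pv)
  attr(pv, "theta_full") <- theta_full
  attr(pv, "theta_loo") <- theta_loo
  pv
}

#' Difference of association matrices between two time points
#'
#' For paired designs (the same subjects measured at two time points), the
#' per-subject network statistic becomes the difference network
#' \eqn{A(t_2) - A(t_1)}; its degree centralities quantify the temporal change
#' in connectivity of each taxon.
#'
#' @param table_t1,table_t2 abundance tables with identical samples (matched
#'   order) and identical taxa.
#' @param ... passed to [sparcc_correlation()].
#' @return p x p matrix of correlation differences (not an association
#'   matrix: diagonal is 0, entries lie in \eqn{[-2, 2]}).
#' @export
paired_difference_association <- function(table_t1, table_t2, ...) {
  t1 <- as.matrix(table_t1); t2 <- as.matrix(table_t2)
  if (!identical(dim(t1), dim(t2))) stop("time-point tables differ in dimension")
  if (!identical(rownames(t1), rownames(t2))) stop("sample mismatch between time points")
  if (!identical(colnames(t1), colnames(t2))) stop("taxon mismatch between time points")
  a1 <- sparcc_correlation(abundance_table(t1), ...)
  a2 <- sparcc_correlation(abundance_table(t2), ...)
  unclass(a2) - unclass(a1)
}

#' Group-specific pseudo-values stacked across two groups
#'
#' Computes jackknife pseudo-values separately within each group (each group
#' with its own sample size and full-sample statistic) and stacks them into a
#' single response matrix aligned with the input sample order. In the paired
#' temporal mode the statistic is the degree centrality of the time-2 minus
#' time-1 difference network and leave-one-out removes the subject from both
#' time points jointly.
#'
#' @param table abundance table (time 1 in the paired mode).
#' @param group integer/factor vector over samples with exactly two levels.
#' @param table_t2 optional time-2 abundance table for the paired mode.
#' @param absolute_degree sum absolute correlations in the degree.
#' @param workers forked workers for leave-one-out loops.
#' @param ... network options passed to [sparcc_correlation()].
#' @return n x p pseudo-value matrix in the original sample order.
#' @export
grouped_pseudovalues <- function(table, group, table_t2 = NULL,
                                 absolute_degree = FALSE, workers = 1L, ...) {
  table <- as.matrix(table)
  lev <- sort(unique(as.character(group)))
  if (length(lev) != 2) stop("group must have exactly 2 levels")
  opts <- list(...)
  if (is.null(table_t2)) {
    estimator <- function(tab) {
      degree_centrality(do.call(sparcc_correlation, c(list(tab), opts)),
                        absolute = absolute_degree)
    }
    make_sub <- function(idx) abundance_table(table[idx, , drop = FALSE])
    pv_of <- function(idx) jackknife_pseudovalues(make_sub(idx), estimator, workers)
  } else {
    t2 <- as.matrix(table_t2)
    if (!identical(rownames(table), rownames(t2)))
      stop("sample mismatch between time points")
    if (!identical(colnames(table), colnames(t2)))
      stop("taxon mismatch between time points")
    # paired statistic: leave-one-out drops the subject from both tables,
    # so the "table" handed to the jackknife is the sample index carrier
    pv_of <- function(idx) {
      sub1 <- table[idx, , drop = FALSE]
      sub2 <- t2[idx, , drop = FALSE]
      estimator <- function(tab) {
        keep <- rownames(tab)
        d <- do.call(paired_difference_association,
                     c(list(abundance_table(sub1[keep, , drop = FALSE]),
                            abundance_table(sub2[keep, , drop = FALSE])), opts))
        if (absolute_degree) d <- abs(d)
        colSums(d)
      }
      jackknife_pseudovalues(abundance_table(sub1), estimator, workers)
    }
  }
  pv <- matrix(NA_real_, nrow(table), ncol(table),
               dimnames = list(rownames(table), colnames(table)))
  for (z in lev) {
    idx <- which(as.character(group) == z)
    pv[idx, ] <- pv_of(idx)
  }
  pv
}
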