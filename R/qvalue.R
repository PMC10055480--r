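#' Q-values for false discovery rate control
#'
#' Storey-type q-values: the estimated null proportion \eqn{\hat\pi_0} is
#' obtained from the empirical p-value distribution by evaluating
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))} on a grid and
#' smoothing it toward \eqn{\lambda = 1} with a cubic smoothing spline; the
#' q-value of each p-value is then the minimum of
#' \eqn{\hat\pi_0\, m\, p_{(j)} / j} over larger-or-equal p-values. When the
#' family is small (fewer than 20 tests) or \eqn{\hat\pi_0} cannot be
#' estimated stably, the conservative \eqn{\hat\pi_0 = 1} is used, for which
#' the q-values reduce exactly to Benjamini-Hochberg adjusted p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param pi0 optionally force the null proportion (e.g. `pi0 = 1` for BH).
#' @return q-values in the input order, each in \[0, 1\], monotone
#'   non-decreasing in p.
#' @export
qvalues <- function(p, pi0 = NULL) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- if (m < 20) 1 else estimate_pi0(p)
  }
  if (!is.finite(pi0) || pi0 <= 0) pi0 <- 1
  pi0 <- min(pi0, 1)
  # step-up with monotone enforcement, scaled by pi0 (pi0 = 1 <=> BH)
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Storey's smoother estimate of the null proportion, clamped into [1/m, 1]:
# an estimate at or below zero means the observed distribution is
# overwhelmingly non-null, so the bound-to-(0,1] floor is small, not 1.
estimate_pi0 <- function(p, lambda = seq(0.05, 0.9, by = 0.05)) {
  m <- length(p)
  floor_pi0 <- 1 / m
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  if (all(pi0_l == 0)) return(floor_pi0)
  fit <- tryCatch(stats::smooth.spline(lambda, pi0_l, df = 3),
                  error = function(e) NULL)
  pi0 <- if (is.null(fit)) pi0_l[length(pi0_l)] else
    stats::predict(fit, x = max(lambda))$y
  if (!is.finite(pi0)) return(1)
  min(max(pi0, floor_pi0), 1)
}
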