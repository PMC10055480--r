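#' Least trimmed squares regression
#'
#' Minimises the sum of the h smallest squared residuals,
#' \eqn{\min_b \sum_{i=1}^h r_{(i)}(b)^2}, which tolerates up to n - h
#' arbitrarily wild observations in response or design. The subset size comes
#' from a trimming proportion c through \eqn{h = \lfloor n(1-c)\rfloor + 1};
#' the default c = 0.5 gives the maximum-breakdown choice
#' \eqn{h = \lfloor n/2\rfloor + 1}.
#'
#' The solver is a seeded randomized search: elemental subsets of
#' (#coefficients) observations are fitted exactly, each followed by
#' concentration steps (refit on the h observations with the currently
#' smallest squared residuals) until the retained subset is stable; the best
#' subset over all starts is kept, so reruns with the same seed are
#' identical.
#'
#' Inference follows the usual reweighted-LTS convention: the raw trimmed fit
#' supplies a consistency-corrected scale estimate, observations whose raw
#' standardized residual exceeds 2.5 are flagged as outliers, and the
#' reported coefficients and classical standard errors come from the
#' least-squares fit on the retained (weight-1) observations, with the
#' residual variance corrected for the 2.5-sigma truncation. When `h = n`
#' no trimming or reweighting happens and the result is the ordinary
#' least-squares fit.
#'
#' @param y numeric response of length n.
#' @param design numeric design matrix including the intercept column.
#' @param trim_c trimming proportion in \[0.5, 1\]; ignored when `h` given.
#' @param h subset size; overrides `trim_c`.
#' @param nsamp number of random elemental starts.
#' @param seed integer seed for the subset search (local RNG; does not
#'   disturb the caller's RNG state).
#' @return list with `coefficients`, `se`, `df` (residual degrees of freedom
#'   of the reported fit), `h`, `best_subset` (raw h-subset indices),
#'   `weights` (0/1 outlier weights), `scale` (corrected residual SD of the
#'   reported fit), `raw_coefficients`, `raw_scale`, and `objective` (sum of
#'   the h smallest squared residuals at the raw fit).
#' @export
lts_fit <- function(y, design, trim_c = 0.5, h = NULL, nsamp = 50L, seed = 1L) {
  X <- as.matrix(design)
  n <- length(y)
  k <- ncol(X)
  if (nrow(X) != n) stop("design/response length mismatch")
  if (n <= k + 1) stop("too few observations for the design")
  if (qr(X)$rank < k) {
    cols <- colnames(X)
    stop("rank-deficient design (collinear columns: ",
         paste(if (is.null(cols)) seq_len(k) else cols, collapse = ", "), ")")
  }
  if (is.null(h)) {
    if (trim_c < 0.5 || trim_c > 1) stop("trim_c must lie in [0.5, 1]")
    h <- floor(n * (1 - trim_c)) + 1L
  }
  h <- as.integer(h)
  if (h < k + 1) h <- k + 1L          # need an over-determined trimmed fit
  if (h > n) h <- n

  cstep_fit <- function(beta) {
    for (rep in 1:30) {
      r2 <- (y - X %*% beta)^2
      sub <- sort.int(order(r2)[seq_len(h)])
      fit <- stats::lm.fit(X[sub, , drop = FALSE], y[sub])
      beta_new <- fit$coefficients
      if (anyNA(beta_new)) return(NULL)
      if (max(abs(beta_new - beta)) < 1e-12) { beta <- beta_new; break }
      beta <- beta_new
    }
    r2 <- (y - X %*% beta)^2
    sub <- sort.int(order(r2)[seq_len(h)])
    list(beta = beta, subset = sub, obj = sum(sort(r2, partial = h)[seq_len(h)]))
  }

  run_search <- function() {
    best <- NULL
    # full LS start is kept as one candidate (optimal when no trimming needed)
    ls0 <- stats::lm.fit(X, y)$coefficients
    if (!anyNA(ls0)) best <- cstep_fit(ls0)
    for (s in seq_len(nsamp)) {
      idx <- sample.int(n, k)
      fit <- tryCatch(stats::lm.fit(X[idx, , drop = FALSE], y[idx]),
                      error = function(e) NULL)
      if (is.null(fit) || anyNA(fit$coefficients)) next
      cand <- cstep_fit(fit$coefficients)
      if (!is.null(cand) && (is.null(best) || cand$obj < best$obj)) best <- cand
    }
    best
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  best <- run_search()
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv())
  if (is.null(best)) stop("LTS search failed to find a non-singular subset")

  sub <- best$subset
  raw_beta <- stats::lm.fit(X[sub, , drop = FALSE], y[sub])$coefficients
  alpha <- h / n
  # variance of a standard normal truncated to its central alpha mass
  # (factor 1 when nothing is trimmed)
  cons_raw <- if (alpha >= 1) 1 else {
    qn <- stats::qnorm((1 + alpha) / 2)
    1 - 2 * qn * stats::dnorm(qn) / alpha
  }
  res_sub <- y[sub] - X[sub, , drop = FALSE] %*% raw_beta
  raw_scale <- sqrt(sum(res_sub^2) / (h - k) / cons_raw)

  if (h >= n) {
    w <- rep(1, n)                         # no trimming requested: plain LS
  } else if (raw_scale <= .Machine$double.eps * max(1, mean(abs(y)))) {
    w <- as.numeric(abs(y - X %*% raw_beta) <= .Machine$double.eps^0.5)
  } else {
    w <- as.numeric(abs(y - X %*% raw_beta) / raw_scale <= 2.5)
  }
  nw <- sum(w)
  if (nw <= k) { w <- rep(1, n); nw <- n }  # pathological: fall back to LS
  keep <- which(w == 1)
  Xw <- X[keep, , drop = FALSE]
  fit <- stats::lm.fit(Xw, y[keep])
  res_w <- fit$residuals
  # truncation correction for discarding |r|/s > 2.5 under normal errors
  cons_w <- if (nw == n) 1 else {
    qw <- 2.5
    1 - 2 * qw * stats::dnorm(qw) / (2 * stats::pnorm(qw) - 1)
  }
  sigma2 <- sum(res_w^2) / max(nw - k, 1) / cons_w
  XtXinv <- chol2inv(chol(crossprod(Xw)))
  se <- sqrt(pmax(diag(XtXinv) * sigma2, 0))
  names(se) <- colnames(X)
  list(coefficients = fit$coefficients, se = se, df = max(nw - k, 1), h = h,
       best_subset = sub, weights = w, scale = sqrt(sigma2),
       raw_coefficients = raw_beta, raw_scale = raw_scale,
       objective = best$obj)
}

#' Wald t-test of a regression coefficient
#'
#' Computes \eqn{U = \hat\beta / SE(\hat\beta)} and its two-sided p-value from
#' the t distribution with the supplied degrees of freedom.
#'
#' @param beta_hat coefficient estimate.
#' @param se its standard error (> 0).
#' @param df degrees of freedom for the t reference.
#' @return list with `U` and `p_value`.
#' @export
test_beta <- function(beta_hat, se, df) {
  if (df < 1) stop("df must be >= 1")
  if (se <= 0) {
    warning("zero standard error; degenerate p-value")
    return(list(U = ifelse(beta_hat == 0, 0, sign(beta_hat) * Inf),
                p_value = ifelse(beta_hat == 0, 1, 0)))
  }
  U <- beta_hat / se
  list(U = U, p_value = 2 * stats::pt(abs(U), df = df, lower.tail = FALSE))
}
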