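#' Variance of log-ratios between all taxon pairs
#'
#' For fractions \eqn{u_{ij}} the statistic \eqn{t_{jk} = Var_i(\log u_{ij}/u_{ik})}
#' is the basic observable of compositional correlation estimation: it can be
#' computed from relative abundances alone yet decomposes, for the latent
#' (basis) abundances, as
#' \eqn{t_{jk} = \sigma_j^2 + \sigma_k^2 - 2\rho_{jk}\sigma_j\sigma_k}.
#'
#' @param fractions strictly positive matrix of relative abundances
#'   (rows = samples), e.g. from [to_fractions()].
#' @return p x p symmetric matrix of log-ratio variances, zero diagonal.
#' @export
logratio_variances <- function(fractions) {
  fractions <- as.matrix(fractions)
  if (any(fractions <= 0)) stop("fractions must be strictly positive")
  n <- nrow(fractions)
  if (n < 2) stop("variance undefined: need at least 2 samples")
  L <- log(fractions)
  # Var(L_j - L_k) = v_j + v_k - 2 cov_jk, from one covariance pass
  C <- stats::cov(L)
  v <- diag(C)
  t <- outer(v, v, "+") - 2 * C
  t <- (t + base::t(t)) / 2     # exact symmetry against FP noise
  t[t < 0] <- 0
  diag(t) <- 0
  dimnames(t) <- list(colnames(fractions), colnames(fractions))
  t
}

#' Basis variances from log-ratio variances
#'
#' Under the sparsity assumption (most pairwise basis correlations are near
#' zero), \eqn{t_{jk} \approx \sigma_j^2 + \sigma_k^2} for pairs still included
#' in the system, so summing over included partners of taxon j gives
#' \eqn{\sum_k M_{jk} t_{jk} = d_j \sigma_j^2 + \sum_k M_{jk}\sigma_k^2} with
#' \eqn{d_j} the number of included partners. This linear system is solved for
#' the per-taxon basis log-abundance variances.
#'
#' @param t symmetric log-ratio variance matrix from [logratio_variances()].
#' @param include optional p x p logical/0-1 matrix marking pairs retained in
#'   the system (default: all off-diagonal pairs).
#' @param floor lower clip applied to the solution; keeps downstream division
#'   by \eqn{\sigma_j} finite for degenerate inputs.
#' @return numeric vector of basis variances, length p.
#' @export
basis_variances <- function(t, include = NULL, floor = 1e-8) {
  t <- as.matrix(t)
  p <- ncol(t)
  if (p < 3) stop("need at least 3 taxa to identify basis variances")
  if (is.null(include)) {
    M <- matrix(1, p, p)
  } else {
    M <- (as.matrix(include) != 0) * 1
  }
  diag(M) <- 0
  d <- rowSums(M)
  if (any(d < 2)) {
    # a taxon with fewer than 2 included partners makes its row ill-posed;
    # re-admit all of its pairs
    M[d < 2, ] <- 1
    M[, d < 2] <- 1
    diag(M) <- 0
    d <- rowSums(M)
  }
  A <- M
  diag(A) <- d
  b <- rowSums(M * t)
  sigma2 <- tryCatch(solve(A, b), error = function(e)
    stop("singular basis-variance system: ", conditionMessage(e)))
  pmax(as.numeric(sigma2), floor)
}

#' SparCC compositional correlation matrix
#'
#' Estimates pairwise taxon-taxon correlations of latent (basis) log
#' abundances from a count table, using the variance-of-log-ratios identity
#' \eqn{\rho_{jk} = (\sigma_j^2 + \sigma_k^2 - t_{jk}) / (2\sigma_j\sigma_k)}
#' with basis variances obtained under the sparsity assumption, then
#' iteratively excluding the strongest correlated pair from the
#' basis-variance system until no newly found pair exceeds
#' `exclusion_threshold` (or the iteration budget is spent).
#'
#' @param table an [abundance_table()].
#' @param pseudocount added to counts before computing fractions (default 0.5;
#'   deterministic zero handling).
#' @param exclusion_threshold absolute correlation above which the strongest
#'   remaining pair is dropped from the basis-variance system each iteration.
#' @param max_exclusion_iters iteration budget for the exclusion loop.
#' @return An `association_matrix`: p x p symmetric correlation matrix with
#'   unit diagonal, entries clipped to \eqn{[-1, 1]}, with attribute
#'   `degenerate = TRUE` when exclusions would have left fewer than 3 taxa in
#'   the system.
#' @export
sparcc_correlation <- function(table, pseudocount = 0.5,
                               exclusion_threshold = 0.1,
                               max_exclusion_iters = 10) {
  table <- as.matrix(table)
  p <- ncol(table)
  if (p < 4) stop("need at least 4 taxa")
  if (nrow(table) < 4) stop("need at least 4 samples")
  fr <- to_fractions(table, pseudocount)
  t <- logratio_variances(fr)

  M <- matrix(1, p, p); diag(M) <- 0
  rho <- NULL
  degenerate <- FALSE
  for (iter in seq_len(max_exclusion_iters + 1L)) {
    sigma2 <- basis_variances(t, include = M)
    s <- sqrt(sigma2)
    rho <- (outer(sigma2, sigma2, "+") - t) / (2 * outer(s, s))
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    if (iter > max_exclusion_iters) break
    # strongest not-yet-excluded pair
    cand <- abs(rho) * M
    diag(cand) <- 0
    m <- max(cand)
    if (m <= exclusion_threshold) break
    idx <- which(cand == m, arr.ind = TRUE)[1, ]
    M2 <- M
    M2[idx[1], idx[2]] <- M2[idx[2], idx[1]] <- 0
    # excluding must leave every taxon with >= 2 partners and the system
    # with >= 3 effective taxa; otherwise stop with the current estimate
    if (any(rowSums(M2) < 2) || sum(rowSums(M2) > 0) < 3) {
      degenerate <- TRUE
      warning("exclusion would degenerate the basis-variance system; returning current estimate")
      break
    }
    M <- M2
  }
  rho <- (rho + base::t(rho)) / 2
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(table), colnames(table))
  structure(rho, class = c("association_matrix", "matrix", "array"),
            degenerate = degenerate)
}

#' @method print association_matrix
#' @export
print.association_matrix <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("association_matrix: %d taxa; |rho| median %.3f, max %.3f\n",
              ncol(x), stats::median(abs(off)), max(abs(off))))
  invisible(x)
}

#' Write an association matrix as a square TSV
#'
#' @param assoc association matrix with taxon dimnames.
#' @param path output file.
#' @export
write_association_tsv <- function(assoc, path) {
  df <- data.frame(taxon_id = rownames(assoc), as.data.frame(unclass(assoc)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an association matrix written by [write_association_tsv()]
#'
#' @param path input file.
#' @return association_matrix.
#' @export
read_association_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  structure(m, class = c("association_matrix", "matrix", "array"))
}
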