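test_that("to_fractions normalises rows and handles zeros via the pseudocount", {
  expect_equal(as.numeric(to_fractions(rbind(c(1, 1, 2)), pseudocount = 0)),
               c(0.25, 0.25, 0.5))
  expect_equal(as.numeric(to_fractions(rbind(c(0, 0)), pseudocount = 0.5)),
               c(0.5, 0.5))
  tab <- toy_counts(8, 5)
  fr <- to_fractions(tab, pseudocount = 0.5)
  expect_equal(unname(rowSums(fr)), rep(1, 8), tolerance = 1e-12)
  expect_true(all(fr > 0))
  expect_error(to_fractions(rbind(c(0, 0)), pseudocount = 0), "degenerate")
})

test_that("log-ratio variances: constant ratios vanish, matrix is symmetric", {
  tab <- toy_counts(10, 4)
  fr <- to_fractions(tab, 0)
  fr2 <- fr
  fr2[, 2] <- 3 * fr2[, 1]            # taxon 2 proportional to taxon 1
  t <- logratio_variances(fr2)
  expect_equal(t[1, 2], 0, tolerance = 1e-12)
  expect_identical(t, t(t))
  expect_true(all(diag(t) == 0))
  expect_error(logratio_variances(fr[1, , drop = FALSE]), "variance undefined")
})

test_that("log-ratio variance of independent unit-variance taxa is near 2", {
  # Monte-Carlo oracle: for independent log-normal bases with sigma^2 = 1,
  # Var(log u_j/u_k) = Var(log a_j) + Var(log a_k) = 2 (composition cancels
  # in the ratio).
  tab <- independent_lognormal_counts(5000, 5, seed = 7)
  t <- logratio_variances(to_fractions(tab, 0))
  off <- t[upper.tri(t)]
  expect_true(all(abs(off - 2) < 0.15))
})

test_that("basis variances solve the sparsity-approximation linear system", {
  # p = 3, all pairwise t = 2: hand/oracle solve of A s = b with
  # A = diag(d) + M, b = row sums.
  t3 <- matrix(2, 3, 3); diag(t3) <- 0
  A <- matrix(1, 3, 3); diag(A) <- 2
  oracle <- solve(A, rowSums(t3))
  expect_equal(basis_variances(t3), as.numeric(oracle), tolerance = 1e-12)
  expect_equal(basis_variances(t3), c(1, 1, 1), tolerance = 1e-12)

  # identical taxa up to scaling: all log-ratio variances zero -> floor
  t0 <- matrix(0, 4, 4)
  expect_equal(basis_variances(t0, floor = 1e-8), rep(1e-8, 4))
})

test_that("basis variances recover known sigma^2 = 1 for independent taxa", {
  tab <- independent_lognormal_counts(5000, 10, seed = 11)
  t <- logratio_variances(to_fractions(tab, 0))
  s2 <- basis_variances(t)
  expect_true(all(abs(s2 - 1) < 0.2))
})

test_that("perfectly proportional taxa get correlation exactly 1", {
  set.seed(3)
  base <- matrix(rlnorm(200 * 4), 200, 4)
  ab <- cbind(base[, 1], 2.5 * base[, 1], base[, 2:4])
  counts <- round(ab / rowSums(ab) * 1e6); counts[counts == 0] <- 1
  rho <- sparcc_correlation(abundance_table(counts), pseudocount = 0)
  # t_12 = 0 so the numerator is sigma1^2 + sigma2^2 >= 2*sigma1*sigma2:
  # the estimate hits the upper clip exactly
  expect_equal(rho[1, 2], 1)
})

test_that("association matrix invariants hold on random tables", {
  for (seed in 1:4) {
    tab <- independent_lognormal_counts(60, 8, seed = seed)
    rho <- sparcc_correlation(tab)
    expect_identical(unclass(rho), t(unclass(rho)))
    expect_equal(unname(diag(rho)), rep(1, 8))
    expect_true(all(rho >= -1 & rho <= 1))
  }
})

test_that("taxon permutation permutes the correlation matrix identically", {
  tab <- independent_lognormal_counts(80, 6, seed = 5)
  rho <- sparcc_correlation(tab)
  perm <- c(3, 1, 6, 2, 5, 4)
  rho_p <- sparcc_correlation(tab[, perm])
  expect_equal(unclass(rho_p), unclass(rho)[perm, perm], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("per-sample count scaling does not change the correlations", {
  tab <- toy_counts(30, 6, seed = 9)
  scaled <- unclass(as.matrix(tab)) * sample(c(1, 10, 100), 30, replace = TRUE)
  rho1 <- sparcc_correlation(tab, pseudocount = 0)
  rho2 <- sparcc_correlation(abundance_table(scaled), pseudocount = 0)
  expect_equal(unclass(rho1), unclass(rho2), tolerance = 1e-10)
})

test_that("independent taxa yield small off-diagonal correlations at n = 1000", {
  tab <- independent_lognormal_counts(1000, 10, seed = 13)
  rho <- sparcc_correlation(tab)
  expect_lt(mean(abs(rho[upper.tri(rho)])), 0.1)
})

test_that("a latent correlation of 0.7 is recovered within the stated band", {
  tab <- correlated_pair_counts(500, p = 10, rho = 0.7, seed = 17)
  rho <- sparcc_correlation(tab)
  expect_gt(rho[1, 2], 0.55)
  expect_lt(rho[1, 2], 0.85)
})

test_that("association matrix TSV round-trips", {
  tab <- toy_counts(20, 5)
  rho <- sparcc_correlation(tab)
  f <- tempfile(fileext = ".tsv")
  write_association_tsv(rho, f)
  back <- read_association_tsv(f)
  expect_equal(unclass(back), unclass(rho), tolerance = 1e-12, ignore_attr = TRUE)
})
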