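# Fixture builders shared across the suite. Everything is generated in code;
# seeds are fixed so failures are reproducible.

# Counts for p independent log-normal basis taxa (no zero inflation): the
# simplest data on which compositional correlation estimates should vanish.
independent_lognormal_counts <- function(n, p, sdlog = 1, depth = 1e6, seed = 1) {
  set.seed(seed)
  ab <- matrix(rlnorm(n * p, meanlog = 0, sdlog = sdlog), n, p)
  counts <- round(ab / rowSums(ab) * depth)
  counts[counts == 0] <- 1
  abundance_table(counts)
}

# Counts where taxa 1 and 2 share latent Gaussian correlation `rho` and the
# remaining taxa are independent: the parameter-recovery fixture.
correlated_pair_counts <- function(n, p = 10, rho = 0.7, sdlog = 1,
                                   depth = 1e6, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * p), n, p)
  z[, 2] <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  ab <- exp(sdlog * z)
  counts <- round(ab / rowSums(ab) * depth)
  counts[counts == 0] <- 1
  abundance_table(counts)
}

# A small deterministic positive count table (no zeros).
toy_counts <- function(n = 6, p = 4, seed = 42) {
  set.seed(seed)
  abundance_table(matrix(sample(50:500, n * p, replace = TRUE), n, p))
}
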