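test_that("the scale-free generator returns a tree with hub concentration", {
  adj <- make_scale_free_adjacency(50, seed = 1)
  expect_identical(dim(adj), c(50L, 50L))
  expect_identical(adj, t(adj))
  expect_true(all(diag(adj) == 0))
  expect_identical(sum(adj) / 2, 49)          # m = 1 attachment: a tree
  hubby <- vapply(1:100, function(s) {
    a <- make_scale_free_adjacency(100, seed = s)
    d <- colSums(a)
    max(d) >= 2 * mean(d)
  }, logical(1))
  expect_gte(mean(hubby), 0.9)
})

test_that("perturbation zeroes exactly the selected rows and columns", {
  adj <- make_scale_free_adjacency(12, seed = 3)
  expect_identical(perturb_adjacency(adj, integer(0)), adj)
  pert <- perturb_adjacency(adj, 5)
  expect_true(all(pert[5, ] == 0) && all(pert[, 5] == 0))
  expect_identical(pert[-5, -5], adj[-5, -5])
  expect_identical(perturb_adjacency(adj, 1:12), matrix(0L, 12, 12))
})

test_that("the truth indicator flags exactly the taxa whose edges differ", {
  adj <- make_scale_free_adjacency(10, seed = 7)
  expect_identical(true_dc_indicator(adj, adj), rep(0L, 10))
  o2 <- adj
  edge <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)[1, ]
  o2[edge[1], edge[2]] <- o2[edge[2], edge[1]] <- 0L
  eta <- true_dc_indicator(adj, o2)
  expected <- rep(0L, 10); expected[edge] <- 1L
  expect_identical(eta, expected)
  perm <- sample(10)
  expect_identical(true_dc_indicator(adj[perm, perm], o2[perm, perm]), eta[perm])
  expect_error(true_dc_indicator(adj * 2, o2), "binary")
})

test_that("metadata marginals match their generating distributions", {
  cfg <- sim_config(age_group_shift = 0)
  md <- generate_metadata(10000, cfg, seed = 5)
  expect_lt(abs(mean(md$X[md$Z == 1]) - 55), 0.5)
  expect_lt(abs(mean(md$Z == 2) - 0.5), 0.02)
  md2 <- generate_metadata(10000, cfg, seed = 5)
  expect_identical(md, md2)
  cfg5 <- sim_config(age_group_shift = 5)
  md3 <- generate_metadata(10000, cfg5, seed = 6)
  expect_lt(abs(mean(md3$X[md3$Z == 2]) - mean(md3$X[md3$Z == 1]) - 5), 0.7)
})

test_that("synthesized counts have the configured zero inflation", {
  cfg <- sim_config(p = 10, n = 1000, setting = "univariable", delta = 0)
  sim <- simulate_replicate(cfg, seed = 8)
  counts <- as.matrix(sim$table)
  expect_true(all(counts >= 0) && all(counts == round(counts)))
  expect_identical(dim(counts), c(1000L, 10L))
  zero_frac <- colMeans(counts == 0)
  expect_true(all(abs(zero_frac - 0.3) < 0.05))
})

test_that("truth-network edges appear as rank correlation in the counts", {
  # compositional closure and zero inflation attenuate the observable
  # correlation of any single pair, so the copula contract is asserted on
  # the mean over edges against the non-edge background
  cfg <- sim_config(p = 20, n = 1000, setting = "univariable", delta = 0,
                    copula_edge_rho = 0.6)
  sim <- simulate_replicate(cfg, seed = 12)
  g1 <- sim$metadata$Z == 1
  counts <- as.matrix(sim$table)[g1, ]
  sp <- cor(log(counts + 0.5), method = "spearman")
  adj <- sim$truth$omega1
  edge_sp <- sp[upper.tri(sp) & adj == 1]
  nonedge_sp <- sp[upper.tri(sp) & adj == 0]
  expect_gt(mean(edge_sp), 0.3)
  expect_lt(abs(mean(nonedge_sp)), 0.1)
  expect_gt(min(edge_sp), max(0, mean(nonedge_sp)))
})

test_that("replicates are deterministic and respect the spike-in bookkeeping", {
  cfg0 <- sim_config(p = 20, n = 50, setting = "multivariable",
                     delta1 = 0, delta2 = 0)
  sim0 <- simulate_replicate(cfg0, seed = 4)
  expect_identical(sim0$truth$eta, rep(0L, 20))
  expect_identical(sim0$truth$omega1, sim0$truth$adjacency)
  expect_identical(sim0$truth$omega2, sim0$truth$adjacency)

  cfg <- sim_config(p = 20, n = 50, setting = "univariable", delta = 0.2)
  sim <- simulate_replicate(cfg, seed = 4)
  expect_identical(length(sim$truth$spiked2), 4L)      # ceiling(0.2 * 20)
  expect_identical(length(sim$truth$spiked1), 0L)
  sim_again <- simulate_replicate(cfg, seed = 4)
  expect_identical(unclass(sim$table), unclass(sim_again$table))
  expect_identical(sim$metadata, sim_again$metadata)
})

test_that("eta marks spiked nodes and their neighbors, and grows with delta", {
  cfg <- sim_config(p = 20, n = 50, setting = "univariable", delta = 0.2)
  sim <- simulate_replicate(cfg, seed = 15)
  adj <- sim$truth$adjacency
  spiked <- sim$truth$spiked2
  # graph traversal oracle: DC taxa = spiked nodes with at least one edge,
  # plus their neighbors
  neigh <- unique(unlist(lapply(spiked, function(k) which(adj[, k] == 1))))
  expected <- sort(unique(c(spiked[colSums(adj)[spiked] > 0], neigh)))
  expect_identical(which(sim$truth$eta == 1L), as.integer(expected))

  etas <- vapply(c(0.05, 0.1, 0.2), function(d) {
    s <- simulate_replicate(sim_config(p = 20, n = 50, setting = "univariable",
                                       delta = d), seed = 23)
    sum(s$truth$eta)
  }, numeric(1))
  expect_true(all(diff(etas) >= 0))
})

test_that("groups are exchangeable when nothing distinguishes them", {
  cfg <- sim_config(p = 10, n = 500, setting = "multivariable",
                    delta1 = 0, delta2 = 0, age_group_shift = 0)
  sim <- simulate_replicate(cfg, seed = 31)
  counts <- as.matrix(sim$table)
  g <- sim$metadata$Z
  pvals <- vapply(seq_len(ncol(counts)), function(j) {
    suppressWarnings(stats::ks.test(counts[g == 1, j], counts[g == 2, j])$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})
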