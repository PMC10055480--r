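small_replicate <- function(seed = 5, n = 40, p = 8) {
  simulate_replicate(sim_config(p = p, n = n, setting = "univariable",
                                delta = 0.25), seed = seed)
}

test_that("the design matrix codes groups 0/1 and expands categoricals", {
  md <- data.frame(grp = c("a", "b", "a", "b"), age = c(50, 60, 55, 65),
                   bmi = c("lean", "obese", "overweight", "lean"))
  des <- build_design(md, "grp", c("age", "bmi"))
  expect_equal(des$z, c(0, 1, 0, 1))
  expect_identical(colnames(des$X),
                   c("(Intercept)", "Z", "age", "bmiobese", "bmioverweight"))
  expect_equal(des$X[, "bmiobese"], c(0, 1, 0, 0))
  md$grp <- c("a", "b", "c", "a")
  expect_error(build_design(md, "grp"), "exactly 2 levels")
  md2 <- data.frame(grp = c("a", "b", "a", "b"), age = c(50, NA, 55, 65))
  expect_error(build_design(md2, "grp", "age"), "missing values")
})

test_that("the pipeline returns one row per taxon with coherent columns", {
  sim <- small_replicate()
  res <- sohpie_dna(sim$table, sim$metadata, "Z", seed = 2)
  expect_s3_class(res, "sohpie_result")
  expect_identical(nrow(res), ncol(sim$table))
  expect_identical(res$taxon_id, colnames(sim$table))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$q_value >= 0 & res$q_value <= 1))
  expect_identical(res$dc, as.integer(res$q_value < 0.05))
  # q monotone in p
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))
})

test_that("the pipeline is deterministic given a seed", {
  sim <- small_replicate(seed = 9)
  r1 <- sohpie_dna(sim$table, sim$metadata, "Z", seed = 31)
  r2 <- sohpie_dna(sim$table, sim$metadata, "Z", seed = 31)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("relabeling the two groups negates beta and keeps the inference", {
  sim <- small_replicate(seed = 13)
  md2 <- sim$metadata
  md2$Z <- 3 - md2$Z                      # 1 <-> 2
  r1 <- sohpie_dna(sim$table, sim$metadata, "Z", seed = 11)
  r2 <- sohpie_dna(sim$table, md2, "Z", seed = 11)
  expect_equal(r2$beta, -r1$beta, tolerance = 1e-8)
  expect_equal(abs(r2$t), abs(r1$t), tolerance = 1e-8)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-8)
  expect_equal(r2$q_value, r1$q_value, tolerance = 1e-8)
})

test_that("covariates enter the model and are reported", {
  sim <- simulate_replicate(sim_config(p = 8, n = 40, setting = "multivariable",
                                       delta1 = 0.25, delta2 = 0.25), seed = 3)
  res <- sohpie_dna(sim$table, sim$metadata, "Z", covariate_cols = "X", seed = 2)
  g <- attr(res, "gamma")
  expect_identical(dim(g), c(8L, 1L))
  expect_identical(colnames(g), "X")
  expect_true(all(is.finite(g)))
})

test_that("the paired temporal mode nulls out identical time points", {
  sim <- small_replicate(seed = 21, n = 30, p = 6)
  # time 2 identical to time 1: every difference network is zero, so
  # pseudo-values are exactly zero and no taxon can be called
  res <- sohpie_dna(sim$table, sim$metadata, "Z", table_t2 = sim$table, seed = 4)
  expect_equal(res$beta, rep(0, 6), tolerance = 1e-10)
  pv <- attr(res, "pseudovalues")
  expect_equal(unclass(pv), matrix(0, 30, 6), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("result tables round-trip through the TSV writer", {
  sim <- small_replicate(seed = 2, n = 30, p = 6)
  res <- sohpie_dna(sim$table, sim$metadata, "Z", seed = 6)
  f <- tempfile(fileext = ".tsv")
  write_result_tsv(res, f, config = list(note = "test"))
  back <- read.table(f, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_identical(nrow(back), nrow(res))
  expect_true(all(diff(back$q_value) >= -1e-12))   # sorted by q
  expect_true(file.exists(paste0(f, ".config.json")))
  side <- jsonlite::read_json(paste0(f, ".config.json"))
  expect_identical(side$n_taxa, 6L)
})
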