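#' Scale-free (Barabasi-Albert) adjacency matrix
#'
#' Preferential-attachment network with one edge per arriving node, i.e. a
#' random tree whose degree distribution follows a power law: a few "hub"
#' taxa concentrate connectivity while most taxa are leaves, the topology
#' commonly assumed for microbial co-abundance networks.
#'
#' @param p number of nodes (taxa).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return p x p symmetric 0/1 matrix with zero diagonal and p - 1 edges.
#' @export
make_scale_free_adjacency <- function(p, seed = NULL) {
  if (p < 2) stop("need at least 2 nodes")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_pa(p, power = 1, m = 1, directed = FALSE)
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  adj <- (adj != 0) * 1L
  diag(adj) <- 0L
  adj
}

#' Remove all edges around a set of nodes
#'
#' Zeroes the rows and columns of the listed nodes, disconnecting them (and
#' only them) from the network; the group-specific truth networks of the
#' simulation are built by perturbing a common scale-free network at that
#' group's spiked taxa.
#'
#' @param adj symmetric 0/1 adjacency matrix.
#' @param node_indices integer indices of nodes to disconnect.
#' @return the perturbed adjacency.
#' @export
perturb_adjacency <- function(adj, node_indices) {
  adj <- as.matrix(adj)
  if (length(node_indices) == 0) return(adj)
  if (any(node_indices < 1 | node_indices > ncol(adj))) stop("node index out of range")
  adj[node_indices, ] <- 0L
  adj[, node_indices] <- 0L
  adj
}

#' True differential-connectivity indicator
#'
#' \eqn{\eta_k = I(\sum_j |\Omega^1_{jk} - \Omega^2_{jk}| > 0)}: a taxon is
#' truly differentially connected iff any of its edges differs between the
#' two group networks.
#'
#' @param omega1,omega2 binary adjacency matrices of equal dimension.
#' @return integer 0/1 vector of length p.
#' @export
true_dc_indicator <- function(omega1, omega2) {
  omega1 <- as.matrix(omega1); omega2 <- as.matrix(omega2)
  if (!identical(dim(omega1), dim(omega2))) stop("adjacency dimensions differ")
  if (!all(omega1 %in% c(0, 1)) || !all(omega2 %in% c(0, 1)))
    stop("adjacencies must be binary")
  as.integer(colSums(abs(omega1 - omega2)) > 0)
}

#' Simulation configuration
#'
#' Collects the knobs of the synthetic-data generator. Defaults encode the
#' study conditions of the simulation design this generator reproduces:
#' groups assigned by a fair coin, age-like covariate \eqn{X \sim N(55, 10^2)}
#' (shifted by `age_group_shift` years in group 2), spike-in proportion
#' \eqn{\delta} per group, copula correlation 0.6 on truth-network edges,
#' 30% zero inflation, standard log-normal marginals, and sequencing depth
#' 1e5 reads per sample.
#'
#' @param p number of taxa (>= 4).
#' @param n total number of samples.
#' @param setting `"multivariable"` (spike-in tied to the continuous
#'   covariate, both groups spiked) or `"univariable"` (spike-in tied to the
#'   group indicator, only group 2 spiked).
#' @param delta1,delta2 spike-in proportions per group; in the univariable
#'   setting supply `delta` instead (group 1 is never spiked there).
#' @param delta convenience alias for the univariable setting.
#' @param copula_edge_rho latent Gaussian correlation placed on each
#'   truth-network edge.
#' @param zero_inflation_prob marginal probability of a structural zero.
#' @param lognormal_mu,lognormal_sigma log-normal marginal parameters.
#' @param sequencing_depth reads per sample used to scale fractions to counts.
#' @param age_mean,age_sd,age_group_shift covariate distribution parameters.
#' @param spike_scale multiplier converting \eqn{\delta} into a log-abundance
#'   mean shift: spiked taxa receive
#'   \eqn{\delta \cdot spike\_scale \cdot \sigma \cdot} (standardised
#'   covariate).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(p = 20, n = 100, setting = c("multivariable", "univariable"),
                       delta1 = 0.2, delta2 = 0.2, delta = NULL,
                       copula_edge_rho = 0.6, zero_inflation_prob = 0.3,
                       lognormal_mu = 0, lognormal_sigma = 1,
                       sequencing_depth = 1e5,
                       age_mean = 55, age_sd = 10, age_group_shift = 5,
                       spike_scale = 2) {
  setting <- match.arg(setting)
  if (p < 4) stop("p must be >= 4")
  if (setting == "univariable") {
    if (!is.null(delta)) delta2 <- delta
    delta1 <- 0
  }
  if (delta1 < 0 || delta1 > 1 || delta2 < 0 || delta2 > 1)
    stop("spike-in proportions must lie in [0, 1]")
  structure(list(p = p, n = n, setting = setting,
                 delta1 = delta1, delta2 = delta2,
                 copula_edge_rho = copula_edge_rho,
                 zero_inflation_prob = zero_inflation_prob,
                 lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
                 sequencing_depth = sequencing_depth,
                 age_mean = age_mean, age_sd = age_sd,
                 age_group_shift = age_group_shift,
                 spike_scale = spike_scale),
            class = "sim_config")
}

#' Generate group labels and the continuous covariate
#'
#' Group labels 1/2 are fair-coin Bernoulli; the age-like covariate is
#' \eqn{N(age\_mean + age\_group\_shift \cdot I(Z=2),\ age\_sd^2)}, so the two
#' groups differ in their covariate distribution when the shift is nonzero.
#'
#' @param n number of samples.
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return data.frame with columns `Z` (1/2) and `X`.
#' @export
generate_metadata <- function(n, config = sim_config(), seed = NULL) {
  if (n < 2) stop("n must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  Z <- stats::rbinom(n, 1, 0.5) + 1L
  X <- stats::rnorm(n, config$age_mean + config$age_group_shift * (Z == 2),
                    config$age_sd)
  data.frame(Z = Z, X = X, row.names = paste0("sample", seq_len(n)))
}

# Latent Gaussian correlation for one group. The truth networks here are
# forests (preferential attachment with one edge per node, perturbed only by
# edge removal), for which the Gaussian Markov construction gives an exactly
# PSD correlation matrix with correlation `rho` on every edge:
# corr(j, k) = rho^distance(j, k) within a tree component, 0 across
# components. A naive identity-plus-rho*adjacency matrix is indefinite
# around hubs and would have to be repaired, distorting the edge
# correlations the truth network is supposed to induce; non-forest
# adjacencies (not produced by this generator) still take that repair path.
copula_correlation <- function(omega, rho) {
  omega <- as.matrix(omega)
  p <- ncol(omega)
  n_edges <- sum(omega) / 2
  g <- igraph::graph_from_adjacency_matrix(omega, mode = "undirected")
  if (igraph::is_forest(g)) {
    d <- igraph::distances(g)
    C <- rho^d              # rho^Inf = 0 across components, rho^0 = 1 on diag
    C[!is.finite(d)] <- 0
    diag(C) <- 1
    return(C)
  }
  C <- diag(p) + rho * omega
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    rep <- Matrix::nearPD(C, corr = TRUE, posd.tol = 1e-6)
    if (!rep$converged) stop("copula correlation matrix could not be repaired to PSD")
    C <- as.matrix(rep$mat)
  }
  C
}

#' Synthesize zero-inflated compositional counts given metadata and truth
#'
#' Emulates a covariate-dependent Gaussian-copula generator with zero-inflated
#' log-normal marginals: per group, latent Gaussian vectors are drawn with
#' correlation `copula_edge_rho` on the edges of that group's truth network;
#' each latent quantile is mapped to a structural zero with probability
#' `zero_inflation_prob` and otherwise to a log-normal abundance whose mean
#' log-abundance is shifted, for spiked taxa, by
#' \eqn{\delta_z \cdot spike\_scale \cdot \sigma} times the standardised
#' covariate (the centred/scaled age in the multivariable setting, the
#' \eqn{\pm 1} group contrast in the univariable setting). Abundances are
#' closed to fractions and scaled to `sequencing_depth` reads.
#'
#' @param config a [sim_config()].
#' @param truth truth specification (list with `omega1`, `omega2`, `spiked1`,
#'   `spiked2`), e.g. from [simulate_replicate()].
#' @param Z group labels (1/2) per sample.
#' @param X continuous covariate per sample.
#' @param seed optional integer seed.
#' @return an [abundance_table()] of non-negative integer counts, n x p.
#' @export
synthesize_counts <- function(config, truth, Z, X, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- config$p
  n <- length(Z)
  stopifnot(length(X) == n)
  pi0 <- config$zero_inflation_prob
  sig <- config$lognormal_sigma
  ab <- matrix(0, n, p)
  for (z in 1:2) {
    idx <- which(Z == z)
    if (!length(idx)) next
    omega <- if (z == 1) truth$omega1 else truth$omega2
    spiked <- if (z == 1) truth$spiked1 else truth$spiked2
    delta <- if (z == 1) config$delta1 else config$delta2
    C <- copula_correlation(omega, config$copula_edge_rho)
    Lc <- chol(C)
    lat <- matrix(stats::rnorm(length(idx) * p), length(idx), p) %*% Lc
    u <- stats::pnorm(lat)
    # per-sample standardised covariate driving the spike-in shift
    std_cov <- if (config$setting == "multivariable") {
      (X[idx] - config$age_mean) / config$age_sd
    } else {
      2 * (Z[idx] - 1.5)        # -1 / +1 group contrast
    }
    mu <- matrix(config$lognormal_mu, length(idx), p)
    if (length(spiked) && delta > 0) {
      shift <- delta * config$spike_scale * sig * std_cov
      mu[, spiked] <- mu[, spiked] + shift
    }
    a <- matrix(0, length(idx), p)
    nz <- u > pi0
    if (any(nz)) {
      q <- (u[nz] - pi0) / (1 - pi0)
      # clip to keep qlnorm finite at the extreme quantile
      q <- pmin(q, 1 - 1e-12)
      a[nz] <- stats::qlnorm(q, meanlog = mu[nz], sdlog = sig)
    }
    ab[idx, ] <- a
  }
  # guard the (vanishingly rare) all-zero sample so closure is defined
  dead <- rowSums(ab) == 0
  if (any(dead)) ab[dead, 1] <- exp(config$lognormal_mu)
  fr <- ab / rowSums(ab)
  counts <- round(fr * config$sequencing_depth)
  abundance_table(counts,
                  sample_ids = paste0("sample", seq_len(n)),
                  taxon_ids = paste0("taxon", seq_len(p)))
}

#' Simulate one complete replicate (truth network, metadata, counts)
#'
#' End-to-end generator: build a scale-free network on p taxa, draw each
#' group's spiked taxon set (\eqn{\lceil \delta_z p\rceil} taxa, uniformly
#' without replacement, independently per group), perturb each group's copy of
#' the network by disconnecting its spiked taxa, derive the true
#' differential-connectivity indicator, generate group labels and covariate,
#' and synthesize the count table. Fully deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `table` (abundance_table), `metadata` (data.frame with
#'   `Z`, `X`), `truth` (list: `omega1`, `omega2`, `spiked1`, `spiked2`,
#'   `eta`) and the `config`.
#' @export
simulate_replicate <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  p <- config$p
  adj <- make_scale_free_adjacency(p)
  n_sp1 <- ceiling(config$delta1 * p)
  n_sp2 <- ceiling(config$delta2 * p)
  spiked1 <- if (n_sp1 > 0) sort(sample.int(p, n_sp1)) else integer(0)
  spiked2 <- if (n_sp2 > 0) sort(sample.int(p, n_sp2)) else integer(0)
  omega1 <- perturb_adjacency(adj, spiked1)
  omega2 <- perturb_adjacency(adj, spiked2)
  eta <- true_dc_indicator(omega1, omega2)
  meta <- generate_metadata(config$n, config)
  table <- synthesize_counts(config, list(omega1 = omega1, omega2 = omega2,
                                          spiked1 = spiked1, spiked2 = spiked2),
                             meta$Z, meta$X)
  list(table = table, metadata = meta,
       truth = list(adjacency = adj, omega1 = omega1, omega2 = omega2,
                    spiked1 = spiked1, spiked2 = spiked2, eta = eta),
       config = config)
}
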