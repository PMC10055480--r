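---
title: "Covariate-adjusted differential co-abundance network analysis with sohpie"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-adjusted differential co-abundance network analysis with sohpie}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microbial co-abundance networks summarize which taxa rise and fall together
across subjects. Comparing such networks between two biological conditions
(differential network analysis) usually reduces to comparing a per-taxon
network statistic — here degree centrality — between groups. Existing
network-comparison tools for microbiome data cannot adjust that comparison
for subject-level covariates such as age or BMI, although the same clinical
factors that shape microbiome composition plausibly shape its network
structure. `sohpie` implements the SOHPIE-DNA approach: turn the per-group
network statistic into subject-level jackknife pseudo-values and put them
into an ordinary (robust) regression with the group indicator and any
covariates.

## The model and the pipeline

**Network estimation.** Counts are compositional, so correlations are
estimated on the latent "basis" scale via the SparCC variance-of-log-ratios
identity. For relative abundances \(u_j\),

\[
t_{jk} = \mathrm{Var}\!\left(\log \frac{u_j}{u_k}\right)
       = \sigma_j^2 + \sigma_k^2 - 2\rho_{jk}\sigma_j\sigma_k,
\]

and under the sparsity assumption (few strong correlations)
\(t_{jk}\approx\sigma_j^2+\sigma_k^2\) for most pairs, which makes the basis
variances \(\sigma_j^2\) solvable from a \(p\times p\) linear system. The
correlation estimate is then

\[
\hat\rho_{jk} = \frac{\hat\sigma_j^2 + \hat\sigma_k^2 - \hat t_{jk}}
                    {2\hat\sigma_j\hat\sigma_k},
\]

clipped to \([-1,1]\). The strongest pair is iteratively excluded from the
basis-variance system (default: pairs above \(|\hat\rho|=0.1\), at most 10
exclusions — the convention of the established SparCC implementations) so
that a few true strong correlations do not contaminate every basis variance.
Zeros are handled by a deterministic pseudocount (default 0.5) rather than
Dirichlet resampling, keeping every estimate — and the whole pipeline —
reproducible bit-for-bit.

**Degree centrality and pseudo-values.** The per-taxon statistic is the
marginal sum \(\hat\theta_k = \sum_j \hat\rho_{jk}\) (the unit diagonal is
included as written; it adds the same constant to every taxon and can only
move the regression intercept). Within each group \(z\) with \(n_z\)
samples, leave-one-out re-estimation of the whole network gives the
jackknife pseudo-values

\[
\tilde\theta_{ik} = n_z\hat\theta_k^z - (n_z-1)\hat\theta_{k(i)}^z ,
\]

which act as approximately independent subject-level observations of the
degree. Pseudo-values are computed within each group separately and stacked;
using the pooled sample instead is known to perform worse and is not
offered as a default.

**Regression and testing.** Per taxon, the stacked pseudo-values are
regressed on an intercept, the 0/1 group indicator and the covariates with
least trimmed squares,

\[
\min_{\alpha_k,\beta_k,\gamma_k} \sum_{i=1}^{h} r_{(i)}^2,
\qquad h = \lfloor n(1-c)\rfloor + 1,\; c\in[0.5,1],
\]

with the maximum-breakdown default \(c=0.5\) (so \(h=\lfloor n/2\rfloor+1\)).
Pseudo-values of a re-estimated network are heavy-tailed — single subjects
can move the network estimate a lot — and trimming is what keeps single wild
pseudo-values from dominating the fit. Inference uses the standard
reweighted-LTS convention: the raw trimmed fit provides a
consistency-corrected scale, observations beyond 2.5 raw standardized
residuals are dropped, and coefficients with classical standard errors come
from the refit on the retained points (variance corrected for the 2.5σ
truncation). The group effect is tested with \(U_k=\hat\beta_k/SE\) against
a t reference, and q-values control the FDR across the \(p\) taxa (Storey's
smoother estimate of the null proportion; with fewer than 20 tests, or when
that estimate is unstable, the conservative \(\pi_0=1\) is used, which is
exactly Benjamini–Hochberg).

**Paired temporal mode.** For designs with the same subjects at two time
points, the statistic becomes the degree of the difference network
\(A(t_2)-A(t_1)\); leave-one-out removes a subject from both time points
jointly, since the per-subject observation is the pair.

## The synthetic-data generator

`simulate_replicate()` reproduces the evaluation design the method was
developed under:

* a scale-free (Barabási–Albert, one edge per node) truth network on `p`
  taxa — a random tree with hub taxa;
* per group, a "spiked" taxon subset (\(\lceil\delta_z p\rceil\) taxa drawn
  uniformly, independently per group) whose rows/columns are removed from
  that group's copy of the adjacency; a taxon is truly differentially
  connected (\(\eta_k=1\)) iff any of its edges differs between groups;
* group labels from a fair coin and an age-like covariate
  \(X\sim N(55,10^2)\), shifted by `age_group_shift` (default 5 years) in
  group 2 so that the covariate distributions differ between groups;
* counts from a zero-inflated log-normal Gaussian copula: latent normals
  with correlation `copula_edge_rho` (default 0.6) on each truth-network
  edge, zero with probability `zero_inflation_prob` (default 0.3), log-normal
  \((\mu=0,\sigma=1)\) otherwise, closed to fractions and scaled to a
  sequencing depth of \(10^5\) reads. Because the truth networks are
  forests, the copula is built exactly as a Gaussian Markov tree
  (correlation \(\rho^{d(j,k)}\) for graph distance \(d\)), which is
  positive definite by construction and places exactly \(\rho\) on every
  edge — no PSD repair that would distort the intended structure;
* spiked taxa receive a mean log-abundance shift of
  \(\delta \cdot \texttt{spike\_scale} \cdot \sigma\) times the standardized
  covariate — the centred and scaled age in the multivariable setting, the
  \(\pm1\) group contrast in the univariable setting. `spike_scale`
  (default 2) is the calibration constant that converts the spike-in
  proportion \(\delta\) into an effect magnitude; it is exposed because no
  canonical value exists for it.

What the generator deliberately does **not** emulate: per-taxon marginal
heterogeneity fitted from a real template (all taxa share \(\mu,\sigma\) and
the zero rate), within-subject correlation over time, and read-level
sampling noise beyond deterministic rounding at depth \(10^5\). Passing
tests on these data therefore demonstrate the mechanics and the statistical
behavior of the pipeline under a controlled truth, not performance on any
particular real cohort.

## Numerical and design choices

* **Printed-formula ambiguity.** The published form of the correlation
  estimator is typeset ambiguously; the only reading consistent with the
  log-ratio variance decomposition is
  \((\hat\sigma_j^2+\hat\sigma_k^2-\hat t_{jk})/(2\hat\sigma_j\hat\sigma_k)\),
  which is what is implemented.
* **Basis-variance floor** of `1e-8` prevents division by zero for
  degenerate inputs (e.g. taxa proportional to each other).
* **Exclusion safeguards.** Exclusion stops (with a warning flag) rather
  than leaving any taxon with fewer than two partners in the basis system.
* **LTS solver.** Seeded elemental-subset search (default 50 starts) with
  concentration steps; the full least-squares start is always included, so
  clean data cannot do worse than least squares. `h = n` disables trimming
  and reduces exactly to ordinary least squares.
* **Degrees of freedom** for the t reference come from the retained
  observations minus the number of coefficients.
* **Categorical covariates** are reference-coded with the lexicographically
  first level as reference; missing covariate values are never imputed —
  samples are dropped and reported.
* **Tie-breaks and determinism.** All randomness (LTS subset search, data
  generation) is controlled by explicit seeds; per-taxon LTS seeds are
  derived as `seed + taxon index`, and replicate seeds as
  `seed + replicate index`, so every number the package produces is
  reproducible from one integer.
* **Undefined metrics.** Zero-discovery replicates have undefined precision
  (0/0); such replicates are excluded from the average of that metric
  rather than counted as zero.

## Problem sizes of the shipped evaluation

The replicated study in `scripts/acceptance.R` and the acceptance tests runs
the three large-effect cells at \(p=20\): univariable \(n=500\) and
multivariable \(n=500\) with 30 replicates each, and univariable \(n=200\)
with 50 replicates — sizes chosen so the whole study completes on a single
CPU in minutes while the replicate means are stable to a few hundredths.

## Known limitations

* **Calibration under the complete null.** The iterative exclusion step
  makes the degree estimator discontinuous: deleting one subject can change
  which pairs are excluded, and the leave-one-out estimates then jump. The
  resulting pseudo-values violate the smoothness that jackknife variance
  estimation relies on, and the per-taxon test becomes strongly
  anti-conservative — in a complete-null simulation (identical group
  generators) far more than 5% of taxa are called at \(q<0.05\). This same
  behavior is what yields the method's characteristically high recall and
  low precision in perturbation studies (most taxa are called once \(n\) is
  large). Setting `max_exclusion_iters = 0` restores a smooth estimator and
  near-nominal null behavior, at the cost of the sparsity correction and of
  sensitivity to network perturbations; the default stays faithful to the
  established SparCC convention. Users who need strict FDR interpretation
  should run both settings.
* **Discoveries should be read as a ranking.** Given the above, q-values
  order taxa usefully, but their absolute scale is optimistic under the
  default network estimator.
* **Two time points only.** The paired mode handles exactly two time points
  and does not model within-subject correlation; generalized estimating
  equations over pseudo-values would be the natural extension.
* **No edge-level inference.** The package tests node centralities, not
  individual edges.

## A worked example

```{r, eval = FALSE}
library(sohpie)

cfg <- sim_config(p = 20, n = 100, setting = "multivariable",
                  delta1 = 0.2, delta2 = 0.2)
sim <- simulate_replicate(cfg, seed = 1)
res <- sohpie_dna(sim$table, sim$metadata, group_col = "Z",
                  covariate_cols = "X", alpha = 0.05, seed = 1)
res
confusion_metrics(sim$truth$eta, res$q_value, alpha = 0.05)
```

The same pipeline is available from the shell via the `inst/cli/sohpie`
entry point (`sohpie simulate`, `sohpie analyze`, `sohpie evaluate`).
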