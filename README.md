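# sohpie

Covariate-adjusted differential co-abundance network analysis for microbiome
count data via jackknife pseudo-values (the SOHPIE-DNA approach).

## What it does, and for whom

Given an OTU/taxon count table and sample metadata with a binary condition
(e.g. disease vs. control), `sohpie` tests **per taxon** whether that taxon's
degree centrality in the microbial co-abundance network differs between the
two conditions, **while adjusting for clinical covariates** such as age, sex
or BMI — something network-comparison tools for microbiome data otherwise do
not support. It is aimed at microbiome researchers doing differential
network analysis on 16S/shotgun-derived count tables.

The machinery:

1. **SparCC network estimation** per group: compositional correlations from
   variances of log-ratios,
   ρ̂ⱼₖ = (σ̂ⱼ² + σ̂ₖ² − t̂ⱼₖ) / (2 σ̂ⱼ σ̂ₖ), with iterative exclusion of
   strong pairs from the basis-variance system.
2. **Jackknife pseudo-values** of degree centrality θ̂ₖ = Σⱼ ρ̂ⱼₖ, computed
   group-specifically: θ̃ᵢₖ = n_z θ̂ₖᶻ − (n_z − 1) θ̂ₖ₍ᵢ₎ᶻ. Each subject gets a
   surrogate observation of the network statistic.
3. **Robust pseudo-value regression** per taxon:
   E[θ̃ᵢₖ] = αₖ + βₖ Zᵢ + Σₘ γₖₘ Xᵢₘ, fitted by least trimmed squares
   (h = ⌊n/2⌋ + 1 by default, reweighted inference); Uₖ = β̂ₖ/SE(β̂ₖ) tests
   H₀: βₖ = 0, and q-values control the FDR across taxa. Taxa with
   q < α are flagged differentially connected (DC).

A paired two-time-point mode replaces the statistic by the degree of the
difference network A(t₂) − A(t₁), for designs such as dietary-intervention
studies. A synthetic-data generator (scale-free truth networks,
group-specific perturbation, zero-inflated log-normal copula counts,
covariate spike-ins) and a replicated evaluation harness
(precision/recall/F1/accuracy against the true DC indicator) are included
and fully tested.

## Worked example

```r
library(sohpie)

cfg <- sim_config(p = 20, n = 100, setting = "multivariable",
                  delta1 = 0.2, delta2 = 0.2)
sim <- simulate_replicate(cfg, seed = 1)      # counts + metadata + truth
res <- sohpie_dna(sim$table, sim$metadata, group_col = "Z",
                  covariate_cols = "X", alpha = 0.05, seed = 1)
res
#> SOHPIE-DNA result: 20 taxa, 12 differentially connected at q < 0.05
#>  taxon_id    beta     se      t   p_value   q_value dc
#>   taxon12 -1.9032 0.2147 -8.863 1.802e-13 1.637e-12  1
#>   taxon20 -1.3407 0.1718 -7.802 1.040e-11 4.721e-11  1
#>   taxon10  0.5587 0.1123  4.976 3.459e-06 1.047e-05  1
#>   ...
confusion_metrics(sim$truth$eta, res$q_value, alpha = 0.05)
#> $precision 0.583  $recall 0.538  $f1 0.56  $accuracy 0.45
#> $n_discoveries 12  $n_true_dc 13
```

`beta` is the estimated change in degree centrality between groups for that
taxon after covariate adjustment, `q_value` its FDR-adjusted significance,
and `dc` the final call at `alpha`. In this replicate 13 of the 20 taxa are
truly differentially connected; 7 of them are recovered among the 12 calls.
Power grows quickly with sample size — the n = 500 cells of the shipped
benchmark reach recall above 0.9.

The same workflows are scriptable from a shell:

```sh
inst/cli/sohpie simulate --p 20 --n 100 --setting multivariable --seed 1 --out out/
inst/cli/sohpie analyze  --counts out/counts.tsv --meta out/metadata.tsv \
                         --group Z --covariates X --seed 1 --out out/
inst/cli/sohpie evaluate --results out/results.tsv --truth out/truth.json
```

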