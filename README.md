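# mixdoc

Direction-of-Causation (DoC) twin models with a finite mixture extension
for detecting *heterogeneous* causal direction between two traits.

## The scientific problem

Two comorbid traits X and Y (say, depression and alcohol use) can be
associated because X causes Y, because Y causes X, because latent factors
confound them — or because the population is a mixture of subgroups with
*opposite* causal directions. The classical twin design identifies causal
direction from the pattern of cross-twin cross-trait covariances: if X
causes Y, cov(x₁, y₂) must mirror the MZ/DZ twin covariance of X, the
causal trait. `mixdoc` fits:

- the homogeneous DoC models (X→Y, Y→X, bidirectional), in which each
  trait has an ACE decomposition (additive genetic, shared environment,
  unique environment) and causal regression paths b carry the cross-trait
  covariance: Σ = (I−B)⁻¹ Ψ (I−B)⁻ᵀ, μ = (I−B)⁻¹ ν;
- the saturated bivariate Cholesky ACE model, which nests the
  unidirectional DoC models;
- a **4-class mixture DoC model**: within each zygosity group, twin pairs
  belong to one of four latent causal-direction classes (both twins X→Y,
  both Y→X, two equated discordant orderings), with class-specific trait
  means, mixing proportions ω (ω₃ = ω₄), and f(y) = Σ_c ω_c φ(y; μ_c, Σ_c).

Models are compared by AIC = −2LL + 2k with raw-data degrees of freedom
(4 data points per pair minus free parameters: 16/14/9/9/10/11 across the
six families). Fitted mixtures yield per-pair posterior class
probabilities and a relative entropy index
Ent = 1 − Σᵢ Σ_c(−p_ic ln p_ic)/(N ln C) ∈ [0, 1] summarizing how
confidently pairs can be assigned to causal classes.

## Worked example

Simulate a heterogeneous population (equal quarters of the four causal
classes, causal effects b = 0.5, class mean-difference parameter 1.0 on
both traits), then compare all six models and classify pairs:

```r
library(mixdoc)

params <- study_params(mean_diff_x = 1, mean_diff_y = 1)   # reconstruction defaults
w      <- mixture_weights(c(0.25, 0.25, 0.25, 0.25))
cfg    <- scenario_config(n_mz = 1000, n_dz = 1000, params, w,
                          family = "mix4", method = "quota", seed = 5)
pairs  <- simulate_dataset(cfg)

ms <- fit_model_set(pairs, n_starts = 3, seed = 1)
ms
#> Model comparison (lowest AIC preferred)
#>      model  k   df minus2ll      aic converged error
#>       mix4 16 7984 25198.43 25230.43      TRUE  <NA>
#>       mix2 14 7986 26152.43 26180.43      TRUE  <NA>
#>     doc_xy  9 7991 26196.49 26214.49      TRUE  <NA>
#>     doc_yx  9 7991 26270.40 26288.40      TRUE  <NA>
#>  doc_bidir 10 7990 26164.53 26184.53      TRUE  <NA>
#>   cholesky 11 7989 26157.53 26179.53      TRUE  <NA>
```

The generating 4-class mixture attains the lowest AIC (25230.4), beating
the best homogeneous model (Cholesky, 26179.5) by ~949 points: the
heterogeneity is clearly detectable. On homogeneous data the ranking flips
and the simpler models win — `run_model_comparison()` replicates either
experiment and tabulates AIC win frequencies.

```r
post <- posterior_probabilities(pairs, ms$fits$mix4)
relative_entropy(post)
#> [1] 0.8416877
head(assign_classes(post), 4)
#>    con_yx dis_xy_yx    con_xy dis_xy_yx
#>         2         3         1         3
```

An entropy of 0.84 says pairs can be assigned to causal classes with high
but not perfect confidence at this class separation; at mean differences
of 1.5 it approaches 1, and at 0.1 it collapses toward 0
(`run_entropy_grid()` sweeps these conditions).

A thin command-line wrapper with `simulate` / `fit` / `compare` /
`posteriors` / `study` subcommands is installed at
`system.file("scripts", "mixdoc", package = "mixdoc")`.

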