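---
title: "Modelling heterogeneous causal direction in twin data with mixdoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heterogeneous causal direction in twin data with mixdoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When two traits co-occur — say depression and alcohol use — the association
may be causal, confounded, or both, and the causal arrow need not point the
same way for everyone. In some people X may drive Y, in others Y may drive
X. Standard causal models assume a homogeneous population; when the
population is in fact a blend of opposite causal processes, a homogeneous
fit returns biased parameters and a misleading conclusion.

The classical twin design gives leverage on causal direction. Monozygotic
(MZ) pairs share essentially all their genetic variants, dizygotic (DZ)
pairs on average half. If X causes Y, the covariance between twin 1's X and
twin 2's Y (the *cross-twin cross-trait* covariance) must echo the twin
covariance of X, the causal trait; if Y causes X it echoes the twin
covariance of Y. When the two traits have sufficiently different modes of
inheritance — different additive-genetic (A), shared-environment (C) and
unique-environment (E) variance compositions — these two predictions
diverge and can be told apart with ordinary maximum likelihood.

`mixdoc` implements the Direction-of-Causation (DoC) family of bivariate
twin models together with a finite Gaussian mixture extension in which the
causal direction is itself a latent class. Because the sampling unit is the
twin *pair* and each member may belong to either causal subpopulation,
there are four classes per zygosity group: both twins X-causes-Y, both
Y-causes-X, and the two discordant orderings. Twin order within a pair is
arbitrary, so the two discordant classes share parameters and mixing
proportion.

## The model

Write the pair vector as $(x_1, y_1, x_2, y_2)$. Within each class, each
trait is built from latent A, C and E factors with loadings
$(a_x, c_x, e_x)$ and $(a_y, c_y, e_y)$, and causal regressions act between
the phenotypes: X-causes-Y contributes the path $b_{xy}$ (y regressed on x
within twin), Y-causes-X the path $b_{yx}$. Collecting the causal paths of
both twins in a $4 \times 4$ matrix $B$ and the pre-causal ACE residual
covariance in $\Psi$, the class-and-zygosity-specific moments follow the
usual reduced form
$$\Sigma = (I-B)^{-1}\,\Psi\,(I-B)^{-\mathsf T}, \qquad
  \mu = (I-B)^{-1}\nu,$$
where $\nu$ holds the structural intercepts of each twin's causal class.
$\Psi$ uses cross-twin factor correlations 1 (MZ A), 0.5 (DZ A), 1 (C) and
0 (E); optional cross-trait factor correlations $r_A, r_C, r_E$ express
latent confounding, applied within twin and — scaled by the factor's twin
correlation — across twins, the standard behaviour-genetic convention.

The mixture density of a pair with zygosity $z$ is
$$f(\mathbf y) = \sum_{c=1}^{4} \omega_{c}^{(z)}\,
  \phi\!\left(\mathbf y;\, \mu_{c}^{(z)}, \Sigma_{c}^{(z)}\right),$$
with $\sum_c \omega^{(z)}_c = 1$ and $\omega_3 = \omega_4$ (discordant
equality). Only three of the five covariance-bearing parameters
($b_{xy}, b_{yx}, r_A, r_C, r_E$) are identified at once; the base mixture
fixes all three $r$'s at zero so that the causal paths carry the
cross-trait covariance, and an extended variant frees $r_A$, equated across
classes. Class separation is carried primarily by class-specific means:
each trait has one mean in the X-causes-Y class and another in the
Y-causes-X class. We parameterize structural intercepts propagated through
$(I-B)^{-1}$ rather than reduced-form means; for unidirectional classes the
two parameterizations are a bijection, so likelihoods are unaffected, and
the intercept form mirrors both the path diagram and the simulator.

Six families are fitted and compared by AIC: the 4-class mixture (16 free
parameters with zygosity-specific proportions), the 2-class concordant-only
mixture (14), the homogeneous unidirectional models X→Y and Y→X (9 each),
the homogeneous bidirectional model (10), and the saturated Cholesky
bivariate ACE model (11), in which each of A, C, E loads on the two traits
through a lower-triangular factor and which nests the unidirectional DoC
models. Degrees of freedom follow raw-data (FIML) accounting,
$\mathrm{df} = \#\text{observations} - \#\text{parameters}$ with 4
observations per pair, and $\mathrm{AIC} = -2\mathrm{LL} + 2k$. (Some
verbal definitions of AIC in this literature read "minus twice the degrees
of freedom", but the $+2k$ convention is the one consistent with the
published model-comparison arithmetic, and is what the package uses
throughout.)

## Classification and entropy

Given a fitted mixture, Bayes' rule yields each pair's posterior class
probabilities $p_{ic} \propto \omega_c \phi_c(\mathbf y_i)$, computed in
log space. Classification quality is summarized by the relative entropy
index
$$\mathrm{Ent} = 1 - \frac{\sum_{i=1}^N \sum_{c=1}^C (-p_{ic}\ln p_{ic})}
  {N \ln C},$$
which is 0 when all posteriors are uniform and 1 when all are degenerate.
By default all pairs are pooled across zygosity groups with $C = 4$: the
sampling unit is the pair and the classes have the same meaning in both
groups; a per-zygosity split is available. For fast property checks the
package can also evaluate posteriors at the *generating* parameter values
("oracle" mode) instead of refitting, which isolates the information
content of the design from estimation noise.

## Estimation

The log-likelihood is maximized by a quasi-Newton optimizer (PORT
routines, `stats::nlminb`) on an unconstrained scale: positive loadings by
the absolute-value convention (loadings are sign-indeterminate, so the
non-negative representative is canonical), strictly positive
unique-environment loadings and Cholesky E-diagonals by log,
correlations by atanh, and mixing proportions by multinomial logits
relative to the discordant class, which builds the $\omega_3 = \omega_4$
constraint into the parameterization and maps equal quarters to logits of
zero. Covariance positive-definiteness is enforced by rejection (a
non-finite or non-PD evaluation returns a large objective value) rather
than penalties.

Starting values are method-of-moments: univariate ACE splits per trait from
the MZ/DZ cross-twin covariances, causal paths from pooled cross-trait
regressions, and mixture class means from a provisional 2-means clustering
of the pair averages. Additional starts perturb the unconstrained vector by
scaled Gaussian noise; the best local optimum wins and exact ties go to the
lowest start index, making results deterministic given data and seed.
Convergence requires the optimizer's relative-tolerance stop plus a
central-difference gradient norm below $10^{-5}(1 + |-2\mathrm{LL}|)$ at
the optimum. The default is 10 starts for one-off fits and 3–4 for
replication studies, where the moment-based start is reliable. Because each
mixture class has a distinct structural identity (which trait causes which,
in which twin), there is no label-switching ambiguity to canonicalize; the
practical multimodality is between direction-swapped local optima, which is
what the multiple starts address. A class weight estimated below $10^{-4}$
is reported as degenerate but the fit is kept.

## The simulator

Two independent sampling paths generate twin pairs and cross-validate one
another. The moment path draws each pair directly from its class's implied
4-variate Gaussian; the structural path draws latent A/C/E factor scores
with the appropriate twin and cross-trait correlations, weights them by the
loadings and solves the phenotypes through $(I-B)^{-1}$. The two paths
agree in distribution, which is tested. Class counts are drawn
multinomially by default; a fixed-quota mode (largest-remainder rounding)
reproduces merged equal-quarter designs exactly and is used for the
replication studies. One root seed drives everything through fixed
per-zygosity, per-class stream offsets, so editing one scenario block does
not cascade into others, and the caller's RNG state is left untouched.

The study defaults (`study_params()`) are documented reconstructions, not
published values: standardized trait variances with contrasting modes of
inheritance (X: $a^2 = 0.7$, $c^2 = 0$, $e^2 = 0.3$; Y: $a^2 = 0.1$,
$c^2 = 0.6$, $e^2 = 0.3$), causal coefficients $b = 0.5$, no confounding,
equal class quarters. The mean-difference convention places the structural
intercepts of the X-causes-Y class at $+\Delta$ and of the Y-causes-X class
at $-\Delta$ on each trait; observed means then separate by $2\Delta$ on
the upstream trait and more on the downstream trait through the causal
path. This convention was adopted because it is the only a-priori-plausible
reading under which the high-separation benchmark condition
($\Delta = 1.5$ on both traits) yields the near-perfect classification
(entropy $\approx 1$) that the design is known to produce; under it the
package measures a mean fitted entropy of about 0.975 at that condition.
Alternative readings (phenotypic means at $\pm\Delta/2$ or $\pm\Delta$)
give markedly lower entropy (about 0.51 and 0.92) and were rejected.

What the simulator does *not* emulate: non-Gaussian class densities
(skewed questionnaire scales can mimic spurious mixtures), measurement
error, missing data patterns, assortative mating, dominance variance, or
gene–environment interplay. Passing tests therefore certify the estimator
and the design's information content under the model's own assumptions,
not robustness to their violation.

## Study drivers and problem sizes

`run_model_comparison()` replicates the simulate–fit–compare cycle and
tabulates AIC win frequencies across the six families;
`run_entropy_grid()` sweeps one design quantity per grid section (mean
differences, causal effect sizes, trait-Y heritability with trait X fixed
at $a^2 = 0.7$, genetic confounding with the $r_A$-free variant fitted)
and averages the entropy index over replications. The package's own test
suite runs the model-comparison experiment at 1 000 pairs per zygosity
with 20 replications and 3 starts, the entropy benchmark at 5 000 pairs
with 10 replications, and parameter recovery at 2 000 + 2 000 pairs with
5 replicate sets; these sizes were chosen as the smallest at which the
qualitative claims are stable, with full-scale runs available through the
exported drivers (the original experiments used 1 000 replications).

## Numerical notes and limitations

Mixture log-densities use log-sum-exp stabilization; the per-class Gaussian
evaluation is compiled (RcppArmadillo) since it is the only hot loop.
Degenerate inputs are handled explicitly: empty datasets simulate to empty
(but refuse to fit), bidirectional coefficient pairs with
$b_{xy} b_{yx} = 1$ are rejected as singular, non-PD class covariances
raise errors naming the class, and $0 \ln 0$ is taken as 0 in the entropy.
Ties in hard class assignment break toward the lower class index with a
warning. AIC comparisons closer than 0.01 are counted as ties in study
reports.

Known limitations: mean-driven class separation is the engine of
classification here, so traits whose class means coincide will classify
poorly regardless of sample size; likelihood-ratio p-values across
different class numbers violate the usual regularity conditions and are
deliberately not reported; standard errors (sandwich or bootstrap) are out
of scope; and ordinal or threshold measurement models are not implemented.
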