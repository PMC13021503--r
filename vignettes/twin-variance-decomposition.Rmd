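---
title: "Twin-design variance decomposition with twinmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin-design variance decomposition with twinmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmorph)
```

## The model

The classical twin design decomposes the phenotypic variance of a trait into
additive genetic (A), shared environmental (C) and unique environmental (E)
components by contrasting monozygotic (MZ) twin pairs, who share their full
genome, with dizygotic (DZ) pairs, who share on average half of their
segregating genes. The generating assumptions are that additive genetic
influences correlate 1 within MZ and 0.5 within DZ pairs, shared
environmental influences correlate 1 within both, and unique environmental
influences (which absorb measurement error) are uncorrelated within pairs.
For a single trait with path coefficients $a$, $c$, $e$ this gives the
two-group covariance structure

$$\operatorname{Var}(y) = a^2 + c^2 + e^2, \qquad
  \operatorname{Cov}_{MZ}(y_1, y_2) = a^2 + c^2, \qquad
  \operatorname{Cov}_{DZ}(y_1, y_2) = \tfrac12 a^2 + c^2,$$

and the reported quantities are the standardized shares
$a^2, c^2, e^2$ (summing to 1), with $a^2$ the narrow-sense heritability.
`twin_ace()` maximizes the two-group multivariate-normal likelihood with a
single grand mean per trait, non-negative path coefficients and a strictly
positive unique-environmental path. `twin_saturated()` provides the
unconstrained per-group moments benchmark (10 parameters in the univariate
two-group case) and `twin_lrt()` the nested model comparisons.

For several traits, each component covariance matrix is parameterized
through its Cholesky factor ($A = XX'$ with $X$ lower triangular, and
likewise for C and E), which keeps every implied matrix positive
semidefinite while decomposing all covariation; standardizing the implied
matrices yields the additive genetic, shared environmental and unique
environmental cross-trait correlations $r_A$, $r_C$, $r_E$
(`twin_cholesky()`, `component_correlations()`). The factorization is a
parameterization, not a causal ordering: all reported quantities are
invariant to trait order, and bivariate fits order traits alphabetically by
convention. Cross-wave analyses treat the same trait measured at two
assessment waves as a correlated trait pair
(`cross_wave_correlations()`), so $r_A$ there measures how far the same
genetic influences act at both ages.

Following the analysis policy for anthropometric batteries, the pairwise
correlation pipeline (`genetic_correlation_matrix()`) fits the AE model
first and confirms with the ACE model: shared environmental variance is
typically too small at twin-study sample sizes for $r_C$ to be estimable,
and the package surfaces that honestly through very wide profile intervals
rather than suppressing the component.

## Means model and preprocessing

Traits are preprocessed the way anthropometric twin analyses do it:
BMI is weight (kg) divided by squared height (m); right-skewed adiposity
traits are natural-log transformed (the base cancels in correlations and
standardized components); and each trait is replaced by the residuals of an
ordinary least-squares regression on exact age, separately by sex and
assessment wave (`compute_bmi()`, `log_transform()`, `residualize_age()`).
The order is fixed: BMI is computed from raw weight and height, then
logged; logging precedes residualization. Because the modelled data are
residualized, the structured fits use a single grand mean per trait across
twins and zygosity groups; the saturated model keeps all means free, so the
mean structure is part of what the likelihood-ratio comparison tests.
Residualization is idempotent and uses complete cases per trait within each
stratum; a factor analysis of the residualized correlations
(`principal_factor()`, iterated principal-axis with varimax rotation,
three factors by default) summarizes the phenotypic structure. The
principal-axis estimator is written in this package (initialized at squared
multiple correlations, Heywood cases clipped and flagged); the rotation is
`stats::varimax`.

## The synthetic cohort generator

Because the study data that motivate this pipeline are available only on
request, every estimator here is validated by parameter recovery from
`simulate_twins()`. The generator draws one stacked vector per pair from a
multivariate normal with exactly the covariance the model assumes
(`implied_pair_covariance()`), adds per-sex means and linear age effects,
and exponentiates log-normal traits. Its built-in design
(`mtfs_design()`) reproduces the Minnesota Twin Family Study composition:
252/233/124/147 complete MZ-male/MZ-female/DZ-male/DZ-female pairs at
intake (1512 children, mean age 11.7, range 10.7–12.8) and 207/161/104/93
pairs at follow-up (males at 14.8, females at 18.1 years). Choices where
the published material gives only summaries:

* ages are drawn uniformly within each wave's printed range and shared by
  co-twins (twins are measured at the same visit); the printed SDs are
  stored with the design as documentation;
* pairs attending the follow-up are the first ones of each cell, giving
  deterministic longitudinal attrition;
* missingness is off by default, with an optional per-trait
  missing-completely-at-random rate to exercise the full-information
  likelihood path;
* cross-wave truths stack the two waves of a trait into one joint
  distribution (`crosswave_truth()`); the shared-environmental cross-wave
  correlation is not published, and `reference_crosswave_truth()` sets it
  to 1 (a stable shared environment). With the published per-wave
  components this implies a male weight cross-wave phenotypic correlation
  of 0.916 and male height 0.88, against printed values of 0.91 and 0.87 —
  an internal consistency check for the choice.

The generator is multivariate normal on the (possibly log) modelled scale,
which is exactly the likelihood's assumption; recovery tests are therefore
sharp in expectation but do not probe robustness to non-normality,
selective attrition that depends on the phenotype, zygosity
misclassification or age-varying effect sizes. Passing recovery says the
estimators are correct under the model, not that the model is true of any
particular cohort.

## Numerical choices

* All fits work on internally standardized data (pooled phenotypic SD per
  trait) so the reported standardized quantities are exactly invariant to
  affine rescaling; estimates are mapped back to the trait scale.
* Optimization is quasi-Newton (L-BFGS-B with non-negativity bounds for the
  univariate paths; BFGS on the unconstrained Cholesky factors) from a
  moment-estimator start plus deterministic jittered restarts; objective
  evaluations use per-missingness-pattern sufficient statistics, so cost is
  independent of sample size and partially observed pairs enter by
  marginalizing their missing elements.
* Profile-likelihood 95% intervals collect the parameter values whose
  profiled $-2\log L$ stays within $\chi^2_1(0.95) = 3.84$ of the minimum,
  clipped to $[0,1]$ for variance shares and $[-1,1]$ for correlations;
  a component estimated at the zero boundary reports a lower limit of
  exactly 0. A parametric-bootstrap percentile interval is available as a
  fallback (`confint(fit, method = "boot")`).
* Likelihood-ratio p-values for dropping one variance component use the
  conventional $\chi^2_1$ reference, which is conservative at the zero
  boundary; the 50:50 mixture-corrected p-value is reported alongside as
  `p_mixture`.
* Correlations at the numerical $\pm 1$ boundary are reported as
  $\pm 1.00$ with a boundary flag; component correlations whose diagonal
  variance is numerically zero are flagged undefined, never fabricated.
* Degenerate inputs fail loudly: non-PSD component matrices, strata with
  fewer than three rows, collinear trait pairs and singular saturated
  moments are all rejected with informative errors, and pairwise failures
  inside the matrix pipeline are recorded and skipped without aborting the
  remaining pairs.

## Validation studies shipped with the package

The test suite regenerates cohorts whose truths are the published MTFS
estimates (`mtfs_components()`, `mtfs_crosswave()`) and verifies recovery:
univariate components at 5,000 pairs per zygosity (within $\pm 0.03$),
cross-wave $r_A$/$r_E$ and phenotypic correlations for male height and
weight and female head length, 95% interval coverage for $a^2$ over 500
replicates at the intake male sample size (252 MZ + 124 DZ pairs), the
non-identifiability of $r_C$ at study-scale n (profile intervals spanning
at least $[-0.9, 0.9]$ in a majority of replicates when true $c^2 = 0.1$),
and recovery of planted linear/volume/craniofacial correlation blocks by
the three-factor varimax solution in at least 95 of 100 replicates. These
problem sizes were chosen to make Monte Carlo error small relative to each
tolerance while keeping the default suite quick to run; the same quantities
are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* Opposite-sex pairs, sex-limitation models, dominance (ADE), assortative
  mating and gene–environment interplay are out of scope; sexes are handled
  by stratification only.
* The factor analysis treats individuals as independent; twin clustering
  inflates its effective sample size, which matters for inference on
  loadings but not for the point structure recovered here.
* The full k-trait joint Cholesky is supported, but the pipeline default is
  pairwise bivariate fits: study-scale samples cannot identify a 20-by-20
  joint model, and the published matrices are themselves pairwise.
* Profile intervals rely on the asymptotic $\chi^2$ calibration; at the
  published sample sizes the shipped coverage study finds them accurate for
  $a^2$, but very small groups may need the bootstrap fallback.
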