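# twinmorph

Classical twin-design variance decomposition for anthropometric traits:
simulation, preprocessing, maximum-likelihood ACE modelling and multivariate
Cholesky genetic correlations, built for researchers in behavior genetics and
epidemiology who want a fully testable version of the standard twin analysis
pipeline.

The package addresses a practical problem of twin studies of body size and
morphology: the individual-level data are usually restricted, so published
heritabilities and genetic correlations cannot be re-derived from raw data.
`twinmorph` therefore couples every estimator to a twin-cohort generator with
exactly the covariance structure the model assumes, so each stage can be
validated by parameter recovery at the published study's design.

## The model

For one trait measured on monozygotic (MZ) and dizygotic (DZ) same-sex twin
pairs, the phenotype is decomposed as additive genetic (A, correlated 1
within MZ and 0.5 within DZ pairs), shared environmental (C, correlated 1 in
both) and unique environmental (E, uncorrelated, includes measurement error)
influences:

    Var(y)        = a² + c² + e²
    Cov_MZ(y1,y2) = a² + c²
    Cov_DZ(y1,y2) = ½a² + c²

`twin_ace()` maximizes the two-group normal likelihood and reports the
standardized shares a², c², e² with profile-likelihood confidence intervals;
`twin_saturated()` and `twin_lrt()` give the model-fit comparisons. For
several traits (or one trait at two assessment waves), `twin_cholesky()`
parameterizes A, C and E through lower-triangular Cholesky factors
(A = XX′), and `component_correlations()` standardizes the implied matrices
into the genetic and environmental cross-trait correlations r_A, r_C, r_E.
`principal_factor()` (iterated principal-axis factoring with varimax
rotation) summarizes the phenotypic correlation structure, and
`run_study()` orchestrates the whole workflow from one seeded configuration.

## Worked example

Simulate a male intake cohort at the built-in Minnesota Twin Family Study
design size (252 MZ + 124 DZ complete pairs) whose generating truth is the
published BMI decomposition (a² = 0.79, c² = 0.12, e² = 0.09), adjust for
age, and refit:

```r
library(twinmorph)

tr  <- reference_truth("bmi", "male", "intake")
coh <- simulate_twins(pair_design(252, 124, sex = "male"), tr, seed = 42)
coh <- residualize_age(coh, "bmi")

fit <- twin_ace(twin_pairs(coh, "bmi"), "ACE")
summary(fit, ci = TRUE)
#> Twin ACE model for bmi
#> Pairs: 252 MZ, 124 DZ;  -2lnL = 3344.465 on 4 parameters
#>    estimate  lower  upper
#> a2   0.7577 0.5491 0.9210
#> c2   0.1500 0.0000 0.3601
#> e2   0.0922 0.0747 0.1142

twin_lrt(twin_ace(twin_pairs(coh, "bmi"), "AE"), fit)
#> LRT AE vs ACE: chi2 = 1.2937, df = 1, p = 0.2554
```

The heritability estimate (0.76, 95% CI 0.55–0.92) recovers the generating
0.79 within sampling error at this study size, the shared-environmental
share has the characteristic 0.00 lower bound, and dropping C is not
rejected at this n — the familiar power problem of separating C from A in
twin data. At 5,000 pairs per zygosity the recovery tightens to ±0.03 (see
the test suite and acceptance script).

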