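# twinace

Classical twin-study variance decomposition for continuous volumetric
phenotypes, built for the setting where monozygotic (MZ) and dizygotic (DZ)
same-sex twin pairs are measured on brain structure volumes and the question
is how much of the phenotypic variance is genetic.

## The model

Phenotypic variance is split into additive genetic (A), shared/common
environmental (C) and unique environmental (E) components (optionally
dominance D in place of C). The design exploits that MZ co-twins share all
their segregating genes while DZ co-twins share half on average, and both
share their common environment. Each twin pair is one observation from a
bivariate normal with exchangeable structure:

    Var(y_i)        = a² + c² + e²
    Cov(y_1, y_2)   = a² + c²        (MZ)
    Cov(y_1, y_2)   = a²/2 + c²      (DZ)

(with dominance: `+ d²` on the diagonal, `+ d²` MZ and `+ d²/4` DZ off the
diagonal). The package fits ACE/AE/CE/E/ADE by maximizing the exact pair
likelihood over unconstrained path coefficients, reports standardized
components (A + C + E = 1) with profile-likelihood 95% CIs, and applies the
usual reduction procedure: when C (or A) is negligible in the ACE fit, the
AE (or CE) model is adopted if a likelihood-ratio test shows no significant
worsening (p > 0.05). Supporting stages: cohort CSV I/O with triplet
expansion, synthetic cohort simulation under the same generative model,
age/sex adjustment by residualization, double-entry intra-pair Pearson
correlations with Fisher-z CIs, Falconer moment estimates
(h² = 2(rMZ − rDZ)), Table-1-style descriptive group tests, and Pearson
agreement between two measurement pipelines.

## Worked example

```r
library(twinace)

# 43 MZ + 19 DZ pairs, standardized A = 0.75, E = 0.25 around 7 cm^3
cfg <- sim_config(n_mz = 43, n_dz = 19, var_a = 0.75, var_c = 0,
                  var_e = 0.25, mean = 7, seed = 2026)
cohort <- generate_cohort(cfg, phenotype = "putamen_volume")

adjusted <- residualize(cohort, "putamen_volume", c("age", "sex"))
intrapair_correlation(adjusted, "putamen_volume", "MZ")
#> rMZ(putamen_volume) r = 0.727 (95% CI 0.546, 0.843), n = 43
intrapair_correlation(adjusted, "putamen_volume", "DZ")
#> rDZ(putamen_volume) r = 0.344 (95% CI -0.130, 0.691), n = 19

sel <- select_model(adjusted, "putamen_volume", ci = TRUE)
sel$selected
#> AE model fit for 'putamen_volume' (43 MZ / 19 DZ pairs)
#>   A = 0.730 (raw 0.6339)  95% CI [0.566, 0.834]
#>   E = 0.270 (raw 0.2344)  95% CI [0.166, 0.434]
#>   -2LL = 298.9419, 3 parameters, converged: TRUE
```

rMZ roughly double rDZ signals additive-genetic influence; the ACE fit puts
the shared-environment fraction at ~0, so the reduction procedure adopts the
AE model and estimates heritability A = 0.73 with a 95% profile CI of
[0.57, 0.83] — recovering the generating value 0.75 at study scale.

The `analysis/` directory walks the full workflow as numbered scripts
(simulate → descriptives → correlations → variance components → method
agreement), writing its tables under `results/`.

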