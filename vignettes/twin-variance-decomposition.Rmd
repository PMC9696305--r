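---
title: "Variance decomposition in the classical twin design: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance decomposition in the classical twin design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and its assumptions

The classical twin design decomposes the variance of a continuous phenotype
— here, brain structure volumes in cm³ — into additive genetic (A),
shared-environmental (C) and unique-environmental (E) sources, using the
contrast between monozygotic (MZ) pairs, who share essentially all their
segregating genes, and same-sex dizygotic (DZ) pairs, who share half on
average. Each complete pair is one draw from a bivariate normal with
exchangeable covariance:

* common variance: `a² + c² + d² + e²`,
* MZ within-pair covariance: `a² + c² + d²`,
* DZ within-pair covariance: `a²/2 + d²/4 + c²`.

The `d²/4` term is the standard biometrical result for dominance between
full siblings. C and D are confounded given only MZ/DZ pairs (both enter
through the two off-diagonals, leaving three identifiable quantities), so
the package supports ACE, the nested reductions AE/CE/E, and ADE — never
ACDE. Underlying assumptions inherited from the design: equal environments
across zygosity, no assortative mating, no gene–environment interaction,
and multivariate normality of the residual phenotype. None of these is
testable inside the package; they are the usual price of the design.

`fit_model()` maximizes the exact pair likelihood (`neg2_loglik()`) over
*path coefficients* `a, c, d, e`, whose squares are the variance
components. This makes non-negativity automatic, requires no constrained
optimizer, and lets boundary solutions (the `0` cells of published
variance-component tables) emerge naturally as a path shrinking to zero.

## Model reduction and hypothesis testing

`select_model()` mirrors common practice: fit ACE; if the standardized C
(or A) estimate is below a negligibility threshold (default 0.05, the
package's reading of "negligible" — configurable), fit AE (or CE) and
accept the reduction when the likelihood-ratio test against ACE has
p > 0.05. If both reductions qualify, the one with the lower −2LL wins,
ties going to AE. The plain chi-squared reference is the default because
it is the convention the reproduced tables use; testing a variance at its
boundary actually follows a 50:50 chi-squared mixture, so
`lrt(..., boundary_mixture = TRUE)` provides the corrected p. Under a true
C = 0, the plain test therefore rejects at about α/2 — a property test
checks this calibration by simulation.

## Confidence intervals

CIs on standardized components are profile-likelihood intervals: the set of
fractions `s` at which the −2LL, re-minimized over total variance, the
split of the remaining `1 − s` among the other components, and the mean
structure, stays within `qchisq(0.95, 1) = 3.841` of the minimum. Bounds
are found by bisection to 1e-4 on the fraction scale and clipped to [0, 1];
a bound that cannot be bracketed inside the unit interval is reported at
the boundary and flagged. Profile intervals are the convention of
mainstream twin-modelling software; delta-method intervals are deliberately
not implemented, since they misbehave exactly where twin components live —
near boundaries.

The same parameterization trick (total variance × simplex split) powers the
profiling; for pre-residualized data the likelihood is evaluated from the
per-zygosity sufficient statistics (n, Σy, Σy², Σy₁y₂), making each
evaluation O(1) in pairs — this is why 200-replicate coverage simulations
run in seconds. The direct O(n) evaluator remains the public surface, and a
test pins the two routes together.

## Covariate adjustment

Volumes decline with age and differ by sex, and co-twins share both, which
inflates intra-pair correlations if ignored. The default pipeline
residualizes the phenotype on age (centered) and sex (female = 0) by OLS
over individuals before both the correlation and the likelihood stages —
matching the "age- and sex-adjusted" convention of the reproduced analysis.
A `by_zygosity` option refits the regression separately per group (the
sensitivity check used when the groups differ in age), and
`covariate_handling = "means_model"` instead estimates the age/sex effects
inside the likelihood, the structural-equation-modelling standard. Which of
the two the original analysis used is not documented; residualization is
the package default and the two routes agree closely on simulated data (a
test asserts agreement of the fitted heritability within 0.02).

## Correlations

Intra-pair correlations default to *double entry* (each pair entered in
both orders), the intraclass-style estimator invariant to the arbitrary
member ordering; single entry under the deterministic ordering (ascending
`twin_index`, ties by `individual_id`) is retained for comparison. CIs are
Fisher-z with n = number of pairs — double entry does not pretend to 2n
observations. Published twin tables rarely state their CI recipe; Fisher-z
is this package's documented convention and printed CIs elsewhere are not
treated as reference values. Cross-method agreement is plain Pearson over
individuals with the t-based p-value.

## The synthetic-cohort generator

Because the motivating study's raw volumes are not deposited, every stage
is exercised on simulated cohorts drawn from exactly the generative model
the inference assumes: pair-level age uniform on 25–75 years (median 50,
IQR 25, matching the reported median ± IQR shape), 29% male pairs (the
reported sex ratio), same-sex pairs by construction, shared c and split
additive values per the MZ/DZ kinship coefficients, and defaults of 43 MZ +
19 DZ pairs. Default covariate effects are β_age = −0.02·√(total variance)
per year (atrophy direction) and β_sex = +0.5·√(total variance) — stand-ins
chosen so the adjustment stage has real signal to remove, since the study
reports no effect sizes. A second measurement channel adds independent
Gaussian noise; by the attenuation formula `r = 1/√(1 + σ²_noise/σ²_signal)`,
noise variance of one third the signal variance lands the cross-method
correlation at 0.87, mid-band of the reported 0.74–0.94 agreement.

What the generator does *not* emulate: measurement error correlated within
pairs (scanner/session effects), non-normal volume distributions, age-
varying heritability, and the statistical non-independence of pairs derived
from triplets. Passing parameter-recovery tests therefore demonstrates
correctness of the estimator under the model's own assumptions, not
robustness to their violation on real MRI data.

One RNG stream per cohort with a fixed variable-by-variable draw order
(MZ block, then DZ block) makes identical seeds give identical cohorts;
this is the determinism contract the pipeline and tests rely on. Per-pair
counter-derived streams (which would additionally make prefixes invariant
to n) were considered and dropped: R has no cheap counter RNG, and nothing
downstream needs prefix invariance.

## Numerical choices

* Multi-start optimization: start 1 from moment estimates (double-entry
  correlations through Falconer's formulas, total sample variance); further
  deterministic starts perturb each path by ±50%. Nelder-Mead with a BFGS
  polish; best −2LL wins, ties to the first start. The likelihood can be
  flat near boundaries, which is what the perturbed starts guard against.
* The phenotype is internally standardized to unit variance before
  optimization and everything is mapped back afterwards; this conditions
  the search and makes scale equivariance (raw variances scale as k²,
  standardized components invariant) exact to floating point.
* Non-positive-definite covariances return `Inf` from the likelihood (and
  a large finite value inside the optimizer), never an exception.
* Problem sizes in tests and the acceptance script — 3000–5000 pairs per
  zygosity for recovery checks, 200 replicates at 500 + 500 pairs for CI
  coverage, ≤ 30 pairs for brute-force grid comparisons — were chosen as
  the smallest sizes at which Monte-Carlo error is comfortably inside the
  stated tolerances.

## Descriptive statistics

The characteristics-table tests delegate to base R (`chisq.test`, pooled
`t.test`, `shapiro.test` — Royston's approximation). Both chi-squared
variants are first class because published 2×2 p-values mix conventions:
reproducing the reference table requires Yates for the sex row and plain
Pearson for the risk-factor rows (with questionnaire denominators 59 MZ /
25 DZ recovered from the printed percentages). The Mann-Whitney exact path
is implemented by enumeration with midranks — base `wilcox.test` declines
exact p-values under ties — and capped at 12 combined observations; larger
samples use the tie-corrected, continuity-corrected normal approximation.
Continuous variables route through a Shapiro-Wilk gate (α = 0.05,
configurable) to the t-test or Mann-Whitney.

## Known limitations

* Univariate phenotypes only: no bivariate/multivariate twin models, no
  sex-limitation or age-moderation models, no Bayesian estimation.
* The triplet expansion deliberately keeps the three derived pairs, so
  likelihoods and CIs downstream of triplet data are mildly anti-
  conservative; a warning is emitted at read time.
* Falconer estimates are heuristics (clipped and renormalized), intended
  for starts and sanity checks.
* Profile CIs assume the chi-squared(1) calibration, which is approximate
  for components estimated at or near 0.
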