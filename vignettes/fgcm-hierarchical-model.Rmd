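---
title: "A two-level hierarchical Bayesian model for fecal glucocorticoid metabolites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-level hierarchical Bayesian model for fecal glucocorticoid metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Fecal glucocorticoid metabolites (fGCMs) are the breakdown products of
glucocorticoid stress hormones excreted in dung, measured in ng per g of
dry fecal matter. They are the standard noninvasive window onto adrenal
activity in wild animals. In long-lived social species such as African
elephants, a natural question is whether aspects of an individual's social
environment — losing the mother, leaving the natal family group, the
number of adult caregivers or of similar-aged companions — shift an
individual's *baseline* glucocorticoid level, over and above the
within-individual fluctuations driven by season, reproduction, and
sampling circumstances.

The design that motivates this package samples each of a few dozen
individually known females repeatedly over about 13 months (roughly 15
samples each, at least two weeks apart), yielding a two-scale data
structure: covariates that are fixed per individual and covariates that
change from sample to sample.

## The model

Write $\bar y_i$ for the mean standardized fGCM concentration of
individual $i$'s samples and $y_{ij}$ for the standardized concentration
of sample $j$ from individual $i$. The model has two coupled levels:

$$\bar y_i \sim \mathrm{Normal}(\mu_i,\ 1/\tau_1),\qquad
\mu_i = \alpha + \beta_1 f_i + \beta_2 m_i + \beta_3 n_i + \beta_4 o_i + \beta_5 a_i$$

$$y_{ij} \sim \mathrm{Normal}(\mu_{ij},\ 1/\tau_2),\qquad
\mu_{ij} = \mu_i + \gamma_1 g_{ij} + \gamma_2 l_{ij} + \gamma_3 s_j +
\gamma_4 t_j + \gamma_5 v_j + \gamma_6 p_{ij} + \gamma_7 z_j + \gamma_8 b_{ij}
\ (+\ \gamma_9 w_{ij})$$

Level 1 regresses individual means on time-invariant covariates: adult
caregivers $f$, age mates $m$, number of samples $n$ (a control for
sampling intensity), orphan status $o$, and non-natal group membership
$a$. Level 2 uses the level-1 fitted mean $\mu_i$ as the individual's
intercept and adds the time-varying covariates: age $g$, lactation $l$,
hours the sample sat on the ground before collection $s$, time of day
$t$, spatial mean NDVI $v$ (food availability), pregnancy $p$, spatial SD
of NDVI $z$ (resource patchiness), years since the mother's death $b$,
and optionally the strongylid fecal egg count $w$. $\tau_1$ and $\tau_2$
are precisions. All covariates and the response are standardized
(z-scored, sample SD), binaries included, so every coefficient is in SD
units.

Two structural points deserve emphasis:

* **The two levels share the data.** $\bar y_i$ is a deterministic
  function of the $y_{ij}$, yet it enters level 1 as data while $\mu_i$
  feeds level 2 as the intercept. This "double use" couples the levels —
  coefficients at both levels inform one another — and is kept
  deliberately, because it *is* the model this package reproduces. It is
  not a random-effects reformulation, and the consequences are
  quantified below.
* **$\mu_i$ is deterministic given covariates.** There is no latent
  per-individual intercept deviation in the fitted model; between-individual
  heterogeneity beyond the covariates is absorbed by $\tau_1$
  at level 1 and leaks into level-2 residuals.

## Priors, sampler, and numerical choices

Priors follow the diffuse BUGS-family convention: Normal(0, 1000²) on
every coefficient and Gamma(0.001, 0.001) on both precisions, adjustable
via `prior_spec()`. The exact hyperparameters behind the original
"uninformative priors" phrasing are a convention choice, not a data fact;
sensitivity analysis is a matter of refitting with a different
`prior_spec()`.

Because the model is conjugate linear-Gaussian, `fit_fgcm()` uses an
exact blocked Gibbs sampler: stacking the level-1 rows
$[\,1, x_i, 0\,]$ (weighted by $\tau_1$) and the level-2 rows
$[\,1, x_i, z_{ij}\,]$ (weighted by $\tau_2$), the full conditional of
$(\alpha, \beta, \gamma)$ is multivariate normal, and each precision has
a gamma full conditional with shape offset $I/2$ or $N/2$ and rate offset
half the level's residual sum of squares. No adaptation or tuning is
needed; the `n_adapt` setting of `mcmc_config()` is recorded only for
protocol fidelity. Default protocol: 3 chains of 100,000 iterations,
10,000 burn-in, no thinning. Chains initialize at zero coefficients and
unit precisions with seeded overdispersed jitter, which gives the
Gelman-Rubin diagnostic something to detect if mixing were ever poor.
Each chain's RNG stream is derived deterministically from one root seed,
so fits are exactly reproducible. Collinear designs are refused up front
with the offending columns named; a design row count of zero is allowed
and returns the prior (used by the prior-dominance tests).

Numerical details worth knowing:

* Residual sums of squares are computed from precomputed cross-products
  (clamped at zero against rounding), so an iteration costs one
  $p \times p$ Cholesky factorization with $p \le 16$, and a full
  published-protocol fit takes seconds.
* Quantiles are equal-tailed over pooled post-burn-in chains. The
  published analysis prints "confidence interval" for what are posterior
  credible intervals; `tidy()` computes equal-tailed credible intervals
  and flags whether the 95% and 50% intervals exclude zero, strictly.
* `remove_outliers()` discards a sample iff it lies strictly more than 3
  sample SDs (n−1 denominator, moments including the candidate) from its
  individual's mean, on the raw ng/g scale, in a single pass. A
  consequence of the sample-SD convention, asserted in the tests: the
  largest attainable deviation among $n$ samples is $(n-1)/\sqrt n$ SDs,
  so no sample can ever be discarded from an individual with 10 or fewer
  samples. Ties at exactly 3 SD are retained. The statistics include the
  candidate point itself — the simplest reading of the rule — and the
  filter is applied exactly once in the pipeline.
* `standardize()` refuses constant columns (a constant covariate is
  unidentifiable after centering) and returns the moments needed to
  invert the transform exactly.
* `build_design()` canonicalizes row order (individuals by id; samples by
  individual, date, id), so the assembled design — and therefore a seeded
  fit — is bit-identical regardless of input row order.

## Convergence and model checks

`gelman_rubin()` implements the corrected (df-adjusted) potential scale
reduction factor on unsplit chains — the same point estimate as the
classic `gelman.diag` — with the conventional < 1.1 threshold exposed in
`convergence_report()`. Identical chains return exactly 1; chains that
are constant but unequal are an error rather than a silent 1. Split-chain
and rank-normalized variants are deliberately out of scope.

`posterior_predictive_check()` replicates both levels' data from each
retained draw ($\bar y^{rep}_i$ from the level-1 likelihood, $y^{rep}_{ij}$
from the level-2 likelihood) and reports four Bayesian p-values: the
proportion of draws in which the replicated mean (or SD) meets or exceeds
the observed one, at each level. The inclusive "$\ge$" convention is
used; with continuous statistics ties have measure zero. Replication
noise is seeded, and precisions are floored at a tiny positive value so
that prior-predictive checks under the diffuse gamma prior remain finite.
Whether the original check replicated $\bar y_i$ directly at level 1 or
aggregated replicated level-2 data is not documented; direct level-1
replication is used here, matching the model's two explicit likelihoods.

## The synthetic-data generator

Real covariate data of this kind are sensitive and not distributable, so
the package ships a generator that emulates the study design rather than
any individual animal:

* **Individuals** (defaults): 37 females, 25 orphans of whom 5 are
  non-natal (non-natal implies orphan), caregivers on {0..4} weighted low,
  age mates on {0..8}, ages uniform on 7–21 years, and for orphans a
  positive years-since-mother's-death at study start.
* **Seasonality**: a daily NDVI series with a dominant semiannual
  harmonic (two wet-season green-ups per year, peaks near early May and
  mid November) modulated by a weaker annual harmonic, plus small noise;
  the spatial-SD series is elevated in proportion to the absolute rate of
  change of the mean — patchiness peaks during green-up and dry-down —
  plus noise. A harmonic base has curvature everywhere, which keeps the
  smoothed series cleanly bimodal.
* **Samples**: counts per individual near 15 ± 4 (floored at 2), days
  placed uniformly subject to the 14-day minimum spacing, ages and
  years-without-mom advancing with the calendar, pregnancy/lactation as
  persistent multi-month episodes, daytime collection fractions, gamma
  hours-on-ground, negative-binomial fecal egg counts.
* **Response**: $y^*_{ij} = \alpha + x_i'\beta + \eta_i + z_{ij}'\gamma +
  \epsilon_{ij}$ with $\eta_i \sim N(0, \sigma_1^2)$ and $\epsilon_{ij}
  \sim N(0, \sigma_2^2)$, covariates standardized across the generated
  study. The random intercept $\eta_i$ is the generative analog of the
  fitted model's level-1 noise: the fitted likelihood on observed means
  is not itself a standard generative law, and this is the simplest
  process whose fitted analog is the two-level model above. Defaults for
  the coefficient truth are the published point estimates (e.g. mean
  NDVI −0.69, NDVI SD 0.79, non-natal −0.41); $\sigma_1 = 0.3$,
  $\sigma_2 = 0.8$ are unpublished magnitudes chosen once so simulated
  studies carry realistic signal.
* **Scale**: $y^*$ is rescaled to exact unit sample SD and mapped to
  ng/g as $95.69 + 30.21\,y^*$, floored at 1 ng/g (the floor is
  essentially never active), so generated concentrations land on the
  published descriptive scale. Because preprocessing re-standardizes the
  observed response, the estimand on the analysis scale is the nominal
  truth divided by the realized SD of $y^*$; the generator records both
  the nominal truth and this exact analysis-scale truth in attributes
  (and `write_study()`'s sidecar), and `recovery_experiment()` scores
  against the latter. With the default truth this divisor is about 1.2,
  so e.g. the −0.69 NDVI effect is about −0.47 on the analysis scale.
* **Outliers**: `inject_outliers()` displaces one sample in each of
  `outlier_count` (default 9) distinct individuals to its individual's
  mean + `outlier_magnitude_sd` (default 8) sample SDs. Displacement
  inflates the SD the point is later judged against — a $k$-SD
  displacement among $n$ samples is caught by the 3-SD rule only when
  $k(1-1/n) > 3\sqrt{1+k^2/n}$, i.e. $k \gtrsim 5.8$ at $n = 15$ — so
  planting targets individuals whose sample count clears the bound and
  the default magnitude is 8 rather than something closer to 3.
* **Seeding**: one root seed; every operation draws from its own
  deterministically derived sub-stream, so regenerating one table never
  perturbs another and whole studies are byte-reproducible.

What the generator does *not* emulate: assay chemistry and extraction
noise beyond the Gaussian residual, spatial raster structure behind the
NDVI summaries, social-network dynamics, and the heavy right tail of real
fGCM data (real deposits contain extreme values many SDs out; the
Gaussian generator produces catchable outliers only where planted).
Passing tests on synthetic data therefore validate the machinery — the
filter, the designs, the sampler, the diagnostics — not the biological
conclusions, and descriptive checks against the generator mirror the
published counts (9 discards in 9 distinct individuals; mean ≈ 95.7 ng/g)
only because the generator is configured to that design.

## Calibration results, honestly stated

Two frequentist calibration properties are exercised at study scale in
the test suite and the acceptance script:

* **Posterior predictive calibration**: fitting data simulated from the
  model's own structure yields all four Bayesian p-values inside
  (0.05, 0.95) in at least 18 of 20 seeded replicates.
* **Parameter recovery**: posterior means land close to the
  analysis-scale truth (absolute bias a few hundredths across
  coefficients) and the signs of the strong effects (|truth| ≥ 0.25 SD:
  non-natal group, age mates, mean NDVI, NDVI SD) are recovered in
  every replicate. Coverage of the 95% credible intervals, however, is
  *anticonservative* for several coefficients — roughly 0.65–0.85
  empirically rather than 0.95. This is a structural property of the
  double-use model, not a sampler defect (the sampler passes exact
  conjugate and dense-grid oracle checks): the individual means re-enter
  as level-1 data carrying no information beyond the level-2 rows, so
  the joint posterior is tighter than the sampling variability warrants,
  and the generator's random intercept $\eta_i$ — absent from the fitted
  model — adds within-individual correlation that level-2 standard
  errors ignore. The package reports this as measured; a random-effects
  reformulation would restore coverage but would no longer be the model
  being reproduced.

## Problem sizes used in the shipped checks

Unit tests run on reduced designs (about 12 individuals, 8 samples each,
2 chains of a few thousand iterations) chosen so the whole suite
exercises every code path in a couple of minutes; the grid-oracle check
uses a 3-individual, 8-sample instance where five-dimensional dense
integration is tractable; the convergence check and the acceptance
script run one full-protocol fit (3 × 100,000 iterations) at the default
37-individual design, which the exact Gibbs sampler completes in
seconds. Recovery and calibration experiments use 20 replicates at study
scale with 2 × 5,000-iteration chains, ample for an exact sampler whose
draws are nearly independent.

## Limitations

* The model inherits the published structure's double use of the data;
  see the coverage discussion above before interpreting interval widths.
* No temporal or spatial autocorrelation, no model selection, no
  effective-sample-size or information-criterion machinery — none of
  these are part of the reproduced analysis.
* NDVI enters as two precomputed columns; raster processing is out of
  scope. Fecal egg counts enter as a numeric covariate; counting-method
  error is not modeled.
* Missing egg counts are handled by row deletion and re-standardization
  in the FEC model only; no imputation anywhere.
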