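# fgcmhier

Hierarchical Bayesian analysis of fecal glucocorticoid metabolite (fGCM)
concentrations in longitudinally sampled wild elephants.

fGCMs — glucocorticoid breakdown products measured in dung, in ng/g dry
weight — are the standard noninvasive proxy for adrenal ("stress")
activity in wildlife. This package is for researchers asking whether
features of an individual's social environment (orphaning, leaving the
natal family group, adult caregivers, age mates) shift *baseline*
glucocorticoid levels, separately from within-individual drivers
(season via NDVI, reproduction, time of day, sample handling). It
implements the full analysis chain for repeated-measures designs of a
few dozen individuals sampled ~15 times each over about a year:

* a **synthetic study generator** that emulates the design (no animal
  data ship with the package): individuals, a bimodal seasonal NDVI
  series, longitudinal samples with ≥ 14-day spacing, and planted
  outliers with known ground truth;
* **preprocessing**: per-individual 3-SD outlier discard (sample SD,
  raw ng/g scale, single pass), z-score standardization of the response
  and every covariate, and assembly of the two-level design;
* an exact **blocked Gibbs sampler** for the two-level model;
* **diagnostics**: Gelman–Rubin corrected PSRF (Rc) and posterior
  predictive Bayesian p-values for the mean and SD of each model level;
* a seeded **pipeline** and a **parameter-recovery harness**.

## The model

With all variables standardized, individual means follow

    ybar_i ~ Normal(mu_i, 1/tau1),  mu_i = alpha + beta' x_i

where `x_i` = (adult caregivers, age mates, number of samples, orphan
status, non-natal group), and single samples follow

    y_ij ~ Normal(mu_ij, 1/tau2),  mu_ij = mu_i + gamma' z_ij

where `z_ij` = (age, lactating, hours on ground, time of day, mean NDVI,
pregnancy, NDVI spatial SD, years since mother's death[, fecal egg
count]). The level-1 fitted mean is the level-2 intercept, so the levels
inform one another; priors are diffuse (Normal(0, 1000²) coefficients,
Gamma(0.001, 0.001) precisions). The model is conjugate linear-Gaussian,
so the Gibbs sampler is exact — the default protocol of 3 chains ×
100,000 iterations (10,000 burn-in) runs in seconds. See the methods
vignette (`vignettes/fgcm-hierarchical-model.Rmd`) for assumptions,
numerical choices, and an honest account of the model's calibration.

## Worked example

```r
library(fgcmhier)

study  <- simulate_study(sim_config(seed = 11))   # 37 elephants, 13 months
filt   <- remove_outliers(study$samples)
nrow(filt$discarded)                              # 9 (the planted outliers)
inputs <- build_design(filt$kept, study$individuals)
fit    <- fit_fgcm(inputs, mcmc = mcmc_config(n_chains = 3,
                                              n_iterations = 20000,
                                              n_burnin = 2000, seed = 11))
tidy(fit)
```

```
   term   covariate   level  estimate conf.low conf.high ...
 2 beta5  with non-n… level1 -0.278   -0.332     -0.223
 3 beta1  adult care… level1 -0.112   -0.157     -0.0664
 4 beta2  age mates   level1 -0.107   -0.152     -0.0610
 ...
 7 gamma5 mean NDVI   level2 -0.523   -0.570     -0.476
14 gamma7 NDVI stand… level2  0.525    0.478      0.572
```

Coefficients are posterior means in SD units with 95% and 50% credible
bounds, ordered by effect size within each model level: here the
generator's truth (non-natal −0.41, mean NDVI −0.69, NDVI SD 0.79 on the
generative scale, ≈ −0.28 / −0.47 / 0.54 after response
re-standardization) is recovered with the right signs and magnitudes.
Convergence and fit checks:

```r
glance(fit)
#>   n_individuals n_samples n_chains n_draws max_rhat converged
#> 1            37       554        3   54000     1.00 TRUE
posterior_predictive_check(fit)
#>   level statistic p_value     # Bayesian p-values; ~0.5 is ideal
#> 1     1 mean        0.547
#> 2     1 sd          0.707
#> 3     2 mean        0.480
#> 4     2 sd          0.551
autoplot(fit)   # forest plot of coefficients by level
```

`run_pipeline()` chains these stages from a config (simulated or CSV
input) and writes the discard audit, standardization parameters,
coefficient summary, diagnostics, and a seeded manifest;
`recovery_experiment()` scores bias, RMSE, interval coverage, and sign
agreement against known truth across replicate studies.

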