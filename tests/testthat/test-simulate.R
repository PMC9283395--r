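# Synthetic study generator: design counts, seasonal structure, sample
# generation, outlier planting, determinism, moment recovery.

test_that("simulate_individuals reproduces the study design and is seeded", {
  cfg <- sim_config(seed = 7)
  ind <- simulate_individuals(cfg)
  expect_equal(nrow(ind), 37)
  expect_equal(sum(ind$o), 25)
  expect_equal(sum(ind$o == 0), 12)
  expect_equal(sum(ind$a), 5)
  expect_true(all(ind$o[ind$a == 1] == 1)) # non-natal only among orphans
  expect_true(all(ind$f %in% 0:4))
  expect_true(all(ind$m %in% 0:8))
  expect_true(all(ind$age0_years >= 7 & ind$age0_years <= 21))
  expect_true(all(ind$b0_years[ind$o == 1] > 0))
  expect_true(all(ind$b0_years[ind$o == 0] == 0))
  expect_identical(ind, simulate_individuals(cfg))
})

test_that("degenerate and invalid simulation configs are handled", {
  ind <- simulate_individuals(sim_config(n_orphans = 0, n_non_natal = 0,
                                         seed = 2))
  expect_true(all(ind$o == 0))
  expect_true(all(ind$b0_years == 0))
  expect_error(sim_config(n_orphans = 40), "n_orphans")
  expect_error(sim_config(n_non_natal = 30), "n_non_natal")
  expect_error(sim_config(min_gap_days = 0), "min_gap_days")
  expect_error(sim_config(fgcm_target_sd_ngg = 0), "fgcm_target_sd_ngg")
  expect_error(sim_config(study_length_days = 10), "study_length_days")
})

test_that("seasonal NDVI is bimodal, positive, transition-linked, seeded", {
  cfg <- sim_config(seed = 5, study_length_days = 365)
  se <- simulate_seasonal_covariates(cfg)
  expect_equal(nrow(se), 365)
  expect_true(all(se$ndvi_mean > 0))
  expect_true(all(se$ndvi_sd > 0))
  sm <- stats::filter(se$ndvi_mean, rep(1 / 31, 31))
  sm <- sm[!is.na(sm)]
  n_max <- sum(diff(sign(diff(sm))) == -2)
  expect_equal(n_max, 2)
  # patchiness rises where the mean changes fastest
  expect_gt(cor(se$ndvi_sd[-1], abs(diff(se$ndvi_mean))), 0.5)
  expect_identical(se, simulate_seasonal_covariates(cfg))
  expect_error(
    simulate_seasonal_covariates(sim_config(study_length_days = 20,
                                            min_gap_days = 5)),
    "30")
})

test_that("simulate_samples respects spacing, covariate laws, and units", {
  cfg <- sim_config(seed = 3)
  ind <- simulate_individuals(cfg)
  se <- simulate_seasonal_covariates(cfg)
  sm <- simulate_samples(ind, se, true_params(), cfg)
  gaps <- tapply(as.numeric(sm$date), sm$individual_id,
                 function(d) min(diff(sort(d))))
  expect_true(all(gaps >= 14))
  expect_true(all(sm$t >= 0 & sm$t < 1))
  expect_true(all(sm$s >= 0))
  expect_true(all(sm$y_ngg > 0))
  # age and years-without-mom advance with the calendar, b = 0 off-orphans
  orphans <- ind$individual_id[ind$o == 1]
  for (id in c(orphans[1], ind$individual_id[ind$o == 0][1])) {
    rows <- sm[sm$individual_id == id, ]
    rows <- rows[order(rows$date), ]
    expect_true(all(diff(rows$g) > 0))
    if (id %in% orphans) expect_true(all(diff(rows$b) > 0))
    else expect_true(all(rows$b == 0))
  }
  # NDVI covariates are read off the seasonal series at the sample date
  day <- as.integer(sm$date - as.Date("2015-04-01")) + 1L
  expect_equal(sm$v, se$ndvi_mean[day])
  expect_equal(sm$z, se$ndvi_sd[day])
  expect_error(simulate_samples(ind, se[1:100, ], true_params(), cfg),
               "seasonal")
})

test_that("noise-free generator collapses to the destandardization center", {
  cfg <- sim_config(seed = 4)
  ind <- simulate_individuals(cfg)
  se <- simulate_seasonal_covariates(cfg)
  p0 <- true_params(alpha = 0, beta = rep(0, 5), gamma = rep(0, 8),
                    sigma1 = 0, sigma2 = 0)
  sm <- simulate_samples(ind, se, p0, cfg)
  expect_true(all(sm$y_ngg == 95.69))
  expect_error(true_params(sigma1 = -1), "sigma")
})

test_that("generated data carry the configured mean-NDVI effect", {
  cfg <- sim_config(n_individuals = 120, n_orphans = 80, n_non_natal = 15,
                    samples_per_individual_mean = 15, seed = 21)
  ind <- simulate_individuals(cfg)
  se <- simulate_seasonal_covariates(cfg)
  sm <- simulate_samples(ind, se, true_params(), cfg)
  ystar <- attr(sm, "y_star")
  vs <- (sm$v - mean(sm$v)) / sd(sm$v)
  slope <- coef(lm(ystar ~ vs))[["vs"]]
  expect_lt(abs(slope - (-0.69)), 0.1)
})

test_that("variance of the generated response decomposes as configured", {
  cfg <- sim_config(n_individuals = 300, n_orphans = 200, n_non_natal = 40,
                    samples_per_individual_mean = 10, seed = 8)
  ind <- simulate_individuals(cfg)
  se <- simulate_seasonal_covariates(cfg)
  p <- true_params()
  sm <- simulate_samples(ind, se, p, cfg)
  total <- var(attr(sm, "y_star"))
  expected <- attr(sm, "lp_var") + p$sigma1^2 + p$sigma2^2
  expect_lt(abs(total - expected) / expected, 0.08)
  expect_equal(attr(sm, "scale_factor"), sd(attr(sm, "y_star")))
  # analysis-scale truth is the nominal truth shrunk by the response SD
  tr <- attr(sm, "analysis_scale_truth")
  expect_equal(tr$gamma, p$gamma / attr(sm, "scale_factor"))
})

test_that("covariate marginals match their configured distributions", {
  cfg <- sim_config(n_individuals = 500, n_orphans = 300, n_non_natal = 50,
                    seed = 13)
  ind <- simulate_individuals(cfg)
  p_f <- chisq.test(tabulate(ind$f + 1, 5),
                    p = fgcmhier:::caregiver_probs)$p.value
  p_m <- chisq.test(tabulate(ind$m + 1, 9),
                    p = fgcmhier:::agemate_probs)$p.value
  expect_gt(p_f, 0.01)
  expect_gt(p_m, 0.01)
  se <- simulate_seasonal_covariates(cfg)
  sm <- simulate_samples(ind, se, true_params(), cfg)
  n_i <- table(sm$individual_id)
  expect_lt(abs(mean(n_i) - 15), 1)
  expect_lt(abs(sd(n_i) - 4), 1.2)
})

test_that("inject_outliers flags distinct individuals and is catchable", {
  study <- simulate_study(sim_config(seed = 6))
  sm <- study$samples
  flagged <- sm[sm$outlier_injected, ]
  expect_equal(nrow(flagged), 9)
  expect_equal(length(unique(flagged$individual_id)), 9)
  filt <- remove_outliers(sm)
  expect_true(all(flagged$sample_id %in% filt$discarded$sample_id))

  clean <- simulate_samples(study$individuals, study$seasonal,
                            true_params(), study$config)
  out0 <- inject_outliers(clean, sim_config(outlier_count = 0, seed = 6))
  expect_false(any(out0$outlier_injected))
  expect_equal(out0$y_ngg, clean$y_ngg)
  expect_error(
    inject_outliers(clean, sim_config(outlier_count = 38, seed = 1)),
    "outlier_count")
})

test_that("planted displacement obeys the analytic catchability bound", {
  # one individual, 15 samples: a k-SD displacement inflates the judged SD
  # to sqrt(1 + k^2/n); k = 5 stays under threshold, k = 8 clears it
  base <- tibble::tibble(
    individual_id = "A", sample_id = sprintf("S%02d", 1:15),
    y_ngg = 100 + c(-7, -6, -5, -4, -3, -2, -1, 0, 1, 2, 3, 4, 5, 6, 7))
  s <- sd(base$y_ngg)
  for (k in c(5, 8)) {
    disp <- base
    disp$y_ngg[8] <- mean(base$y_ngg) + k * s
    res <- remove_outliers(disp)
    if (k * (1 - 1 / 15) > 3 * sqrt(1 + k^2 / 15)) {
      expect_equal(res$discarded$sample_id, "S08")
    } else {
      expect_equal(nrow(res$discarded), 0)
    }
  }
})

test_that("a full study is reproducible end to end from one seed", {
  s1 <- simulate_study(sim_config(seed = 17))
  s2 <- simulate_study(sim_config(seed = 17))
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$individuals, s2$individuals)
  s3 <- simulate_study(sim_config(seed = 18))
  expect_false(identical(s1$samples$y_ngg, s3$samples$y_ngg))
})
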