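# Configuration objects: simulation design, generative truth, priors, MCMC.

#' Simulation design configuration
#'
#' Describes a longitudinal dung-sampling study design: how many elephants,
#' how many of them orphans and non-natal (orphans who left their birth
#' family's core group), the sampling intensity and spacing, the target
#' scale of fGCM concentrations, and how many contaminating outliers to
#' plant. The defaults mirror the study design this package emulates:
#' 37 females (25 orphans, 5 of them non-natal), ages 7-21 years, about
#' 15 +/- 4 samples each across a 13-month window with at least 14 days
#' between samples from the same individual, fGCM concentrations around
#' 95.69 ng/g (SD 30.21 ng/g) dry weight, and 9 planted outliers.
#'
#' @param n_individuals number of study subjects.
#' @param n_orphans number of orphans (mother died before subject's first
#'   birth); must not exceed `n_individuals`.
#' @param n_non_natal number of non-natal subjects; all non-natal subjects
#'   are orphans, so this must not exceed `n_orphans`.
#' @param age_range_years length-2 numeric, ages at study start.
#' @param samples_per_individual_mean,samples_per_individual_sd mean and SD
#'   of the per-individual sample count (floored at 2).
#' @param study_length_days length of the collection window in days.
#' @param min_gap_days minimum spacing, in days, between two samples from
#'   the same individual.
#' @param fgcm_target_mean_ngg,fgcm_target_sd_ngg realized mean and SD of
#'   the generated fGCM concentrations, ng/g dry weight.
#' @param outlier_count number of outlier samples planted by
#'   [inject_outliers()], at most one per individual.
#' @param outlier_magnitude_sd displacement of each planted outlier in
#'   multiples of that individual's sample SD. The default 8 guarantees the
#'   planted point exceeds the recomputed 3-SD threshold for individuals
#'   with a dozen or more samples (displacing a point inflates the SD it is
#'   judged against, so magnitudes near 3 are not recoverable).
#' @param seed integer root seed; every generator operation derives its own
#'   deterministic sub-stream from it.
#' @return A validated list of class `fgcm_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_orphans
sim_config <- function(n_individuals = 37,
                       n_orphans = 25,
                       n_non_natal = 5,
                       age_range_years = c(7, 21),
                       samples_per_individual_mean = 15,
                       samples_per_individual_sd = 4,
                       study_length_days = 396,
                       min_gap_days = 14,
                       fgcm_target_mean_ngg = 95.69,
                       fgcm_target_sd_ngg = 30.21,
                       outlier_count = 9,
                       outlier_magnitude_sd = 8,
                       seed = 1L) {
  cfg <- list(
    n_individuals = n_individuals, n_orphans = n_orphans,
    n_non_natal = n_non_natal, age_range_years = as.numeric(age_range_years),
    samples_per_individual_mean = samples_per_individual_mean,
    samples_per_individual_sd = samples_per_individual_sd,
    study_length_days = study_length_days, min_gap_days = min_gap_days,
    fgcm_target_mean_ngg = fgcm_target_mean_ngg,
    fgcm_target_sd_ngg = fgcm_target_sd_ngg,
    outlier_count = outlier_count,
    outlier_magnitude_sd = outlier_magnitude_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "fgcm_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  for (f in c("n_individuals", "n_orphans", "n_non_natal",
              "study_length_days", "min_gap_days", "outlier_count")) {
    if (!is_count(cfg[[f]])) {
      abort_config(sprintf("`%s` must be a non-negative whole number", f))
    }
  }
  if (cfg$n_orphans > cfg$n_individuals) {
    abort_config("invalid counts: n_orphans must be <= n_individuals")
  }
  if (cfg$n_non_natal > cfg$n_orphans) {
    abort_config("invalid counts: n_non_natal must be <= n_orphans")
  }
  if (cfg$min_gap_days < 1) {
    abort_config("min_gap_days must be >= 1")
  }
  if (cfg$study_length_days <= cfg$min_gap_days) {
    abort_config("study_length_days must exceed min_gap_days")
  }
  if (cfg$fgcm_target_sd_ngg <= 0) {
    abort_config("fgcm_target_sd_ngg must be > 0")
  }
  if (length(cfg$age_range_years) != 2 ||
      diff(cfg$age_range_years) <= 0 || cfg$age_range_years[1] <= 0) {
    abort_config("age_range_years must be an increasing positive pair")
  }
  if (cfg$samples_per_individual_mean < 2) {
    abort_config("samples_per_individual_mean must be >= 2")
  }
  cfg
}

#' Generative truth for the two-level model
#'
#' The coefficients that generate standardized fGCM responses. Level 1
#' (between individuals): `beta[1]` adult caregivers, `beta[2]` age mates,
#' `beta[3]` number of samples, `beta[4]` orphan status, `beta[5]` non-natal
#' group. Level 2 (within individuals): `gamma[1]` age, `gamma[2]` lactating,
#' `gamma[3]` time the sample sat on the ground, `gamma[4]` time of day,
#' `gamma[5]` mean NDVI, `gamma[6]` pregnancy, `gamma[7]` NDVI spatial SD,
#' `gamma[8]` years since the mother's death, and optionally `gamma[9]`
#' strongylid fecal egg count. Defaults are the point estimates of the
#' published analysis this package emulates; all act on the standardized
#' (z-score) scale.
#'
#' `sigma1` is the SD of the individual-level intercept deviation (a random
#' intercept in the generator) and `sigma2` the residual SD of single
#' samples, both in standardized units. Their magnitudes are not published;
#' the defaults are chosen so that simulated studies carry realistic signal
#' for recovery experiments.
#'
#' @param alpha intercept on the standardized scale (0: responses are
#'   centered).
#' @param beta numeric length 5, level-1 coefficients.
#' @param gamma numeric length 8 or 9, level-2 coefficients.
#' @param sigma1,sigma2 positive SDs of the individual intercept and the
#'   sample-level residual, standardized units.
#' @return A validated list of class `fgcm_true_params`.
#' @export
#' @examples
#' true_params()$gamma[5] # mean-NDVI effect
true_params <- function(alpha = 0,
                        beta = c(-0.09, -0.25, -0.14, 0.06, -0.41),
                        gamma = c(-0.06, -0.10, 0.09, 0.02, -0.69,
                                  0.08, 0.79, 0.07),
                        sigma1 = 0.3,
                        sigma2 = 0.8) {
  p <- list(alpha = alpha, beta = as.numeric(beta),
            gamma = as.numeric(gamma),
            sigma1 = sigma1, sigma2 = sigma2)
  class(p) <- "fgcm_true_params"
  if (length(p$beta) != 5) abort_config("beta must have length exactly 5")
  if (!length(p$gamma) %in% c(8, 9)) {
    abort_config("gamma must have length 8 or 9")
  }
  if (p$sigma1 < 0 || p$sigma2 < 0) {
    abort_config("sigma1 and sigma2 must be non-negative")
  }
  p
}

#' Prior specification
#'
#' Diffuse priors in the convention of BUGS-family samplers: independent
#' Normal(mean, sd^2) on every regression coefficient and Gamma(shape, rate)
#' on the two precision parameters.
#'
#' @param coef_prior_mean,coef_prior_sd normal prior on coefficients
#'   (default mean 0, sd 1000).
#' @param precision_shape,precision_rate gamma prior on precisions
#'   (default 0.001, 0.001).
#' @return A list of class `fgcm_prior_spec`.
#' @export
prior_spec <- function(coef_prior_mean = 0, coef_prior_sd = 1000,
                       precision_shape = 0.001, precision_rate = 0.001) {
  if (coef_prior_sd <= 0) abort_config("coef_prior_sd must be > 0")
  if (precision_shape <= 0 || precision_rate <= 0) {
    abort_config("precision_shape and precision_rate must be > 0")
  }
  structure(list(coef_prior_mean = coef_prior_mean,
                 coef_prior_sd = coef_prior_sd,
                 precision_shape = precision_shape,
                 precision_rate = precision_rate),
            class = "fgcm_prior_spec")
}

#' MCMC configuration
#'
#' Defaults follow the published protocol: three parallel chains of 100,000
#' iterations with 1000 adaptation iterations and 10,000 discarded as
#' burn-in, no thinning. The blocked Gibbs sampler used here is exact and
#' needs no adaptation; `n_adapt` is recorded for protocol fidelity and is
#' a no-op.
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_iterations post-adaptation iterations per chain.
#' @param n_adapt adaptation iterations (recorded; unused by the Gibbs
#'   sampler).
#' @param n_burnin iterations discarded from the start of each chain.
#' @param thin keep every `thin`-th retained draw.
#' @param seed integer root seed; chain seeds are derived from it.
#' @return A list of class `fgcm_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iterations = 100000, n_adapt = 1000,
                        n_burnin = 10000, thin = 1, seed = 1L) {
  cfg <- structure(list(n_chains = n_chains, n_iterations = n_iterations,
                        n_adapt = n_adapt, n_burnin = n_burnin, thin = thin,
                        seed = as.integer(seed)),
                   class = "fgcm_mcmc_config")
  if (!is_count(cfg$n_chains) || cfg$n_chains < 1) {
    abort_config("n_chains must be a positive whole number")
  }
  if (cfg$n_burnin + 1 >= cfg$n_iterations) {
    abort_config("n_iterations must exceed n_burnin + 1 (no retained draws)")
  }
  if (!is_count(cfg$thin) || cfg$thin < 1) abort_config("thin must be >= 1")
  cfg
}

#' Read a simulation or pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments of [sim_config()], [prior_spec()],
#' [mcmc_config()] under `simulation`, `priors` and `mcmc`; unknown keys are
#' an error. Top-level scalar keys `include_fec`, `output_dir`, `samples`
#' and `individuals` (input CSV paths) are passed through.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list with validated `simulation`, `priors`, `mcmc`
#'   entries where present.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_validation(paste("no such config file:", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("simulation", "priors", "mcmc", "include_fec", "output_dir",
             "samples", "individuals", "params")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    abort_config(paste("unknown config keys:", paste(bad, collapse = ", ")))
  }
  out <- raw
  if (!is.null(raw$simulation)) {
    out$simulation <- do.call(sim_config, as.list(raw$simulation))
  }
  if (!is.null(raw$priors)) out$priors <- do.call(prior_spec, as.list(raw$priors))
  if (!is.null(raw$mcmc)) out$mcmc <- do.call(mcmc_config, as.list(raw$mcmc))
  if (!is.null(raw$params)) out$params <- do.call(true_params, as.list(raw$params))
  out
}
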