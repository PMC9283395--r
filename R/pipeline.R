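# End-to-end pipeline: simulate/read -> filter -> standardize -> fit ->
# diagnose -> report, and a parameter-recovery harness.

stage <- function(name, code) {
  tryCatch(force(code), error = function(e) {
    rlang::abort(sprintf("pipeline stage `%s` failed: %s", name,
                         conditionMessage(e)),
                 class = "fgcmhier_pipeline_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Either simulates a study (`config$simulation` set) or reads the two
#' input CSVs (`config$samples` / `config$individuals` set) — exactly one
#' input mode — then applies the per-individual 3-SD outlier discard,
#' standardizes all covariates and the response, fits the two-level model
#' by Gibbs sampling, and runs convergence and posterior predictive
#' checks. All artifacts are written to `config$output_dir`:
#' `discarded_samples.csv`, `standardization.json`,
#' `coefficient_summary.csv`, `convergence.json`, `ppc.json`, and
#' `manifest.json` (seed, config hash, package/R versions). Reruns with
#' the same config and seed reproduce every numeric output.
#'
#' @param config a list (or [read_pipeline_config()] result) with either
#'   `simulation` (a [sim_config()]) plus optional `params`
#'   (a [true_params()]), or `samples`/`individuals` CSV paths; optional
#'   `priors`, `mcmc`, `include_fec`, and `output_dir` (required).
#' @return Invisibly, a list with `inputs`, `fit`, `summary`,
#'   `convergence`, `ppc`, `discarded`, `paths`.
#' @export
run_pipeline <- function(config) {
  has_sim <- !is.null(config$simulation)
  has_files <- !is.null(config$samples) || !is.null(config$individuals)
  if (has_sim == has_files) {
    abort_config("exactly one input mode: `simulation` or `samples`+`individuals`")
  }
  if (is.null(config$output_dir)) abort_config("config$output_dir is required")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  priors <- config$priors %||% prior_spec()
  mcmc <- config$mcmc %||% mcmc_config()
  include_fec <- isTRUE(config$include_fec)

  data <- if (has_sim) {
    stage("simulate", {
      st <- simulate_study(config$simulation,
                           config$params %||% true_params(
                             gamma = if (include_fec) {
                               c(true_params()$gamma, 0.1)
                             } else true_params()$gamma))
      list(samples = st$samples, individuals = st$individuals)
    })
  } else {
    stage("read", read_fgcm_tables(config$samples, config$individuals))
  }

  filtered <- stage("outlier_filter", remove_outliers(data$samples))
  inputs <- stage("design", build_design(filtered$kept, data$individuals,
                                         include_fec = include_fec))
  fit <- stage("fit", fit_fgcm(inputs, priors = priors, mcmc = mcmc))
  conv <- stage("diagnose", convergence_report(fit))
  ppc <- stage("diagnose", posterior_predictive_check(fit))
  summary_tbl <- tidy(fit)

  paths <- list(
    discarded = file.path(config$output_dir, "discarded_samples.csv"),
    standardization = file.path(config$output_dir, "standardization.json"),
    summary = file.path(config$output_dir, "coefficient_summary.csv"),
    convergence = file.path(config$output_dir, "convergence.json"),
    ppc = file.path(config$output_dir, "ppc.json"),
    manifest = file.path(config$output_dir, "manifest.json")
  )
  stage("report", {
    readr::write_csv(filtered$discarded, paths$discarded)
    jsonlite::write_json(inputs$standardization, paths$standardization,
                         dataframe = "rows", digits = NA)
    readr::write_csv(summary_tbl, paths$summary)
    jsonlite::write_json(
      list(threshold = attr(conv, "threshold"),
           all_converged = all(conv$converged),
           parameters = conv),
      paths$convergence, dataframe = "rows", auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(n_draws_used = attr(ppc, "n_draws_used"),
           checks = as.data.frame(ppc)),
      paths$ppc, dataframe = "rows", auto_unbox = TRUE, digits = NA)
    hashable <- config
    hashable$output_dir <- NULL
    jsonlite::write_json(
      list(seed = if (has_sim) config$simulation$seed else mcmc$seed,
           mcmc_seed = mcmc$seed,
           config_hash = rlang::hash(hashable),
           include_fec = include_fec,
           n_discarded = nrow(filtered$discarded),
           n_kept = nrow(filtered$kept),
           package_version = as.character(utils::packageVersion("fgcmhier")),
           r_version = paste(R.version$major, R.version$minor, sep = ".")),
      paths$manifest, auto_unbox = TRUE, digits = NA)
  })
  invisible(list(inputs = inputs, fit = fit, summary = summary_tbl,
                 convergence = conv, ppc = ppc,
                 discarded = filtered$discarded, paths = paths))
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a study with known generative truth, runs the full
#' preprocessing + fitting chain, and scores how well the posterior
#' recovers the truth on the analysis (re-standardized) scale: mean bias,
#' RMSE, empirical coverage of the 95% credible interval, and sign
#' agreement of the posterior mean, per coefficient.
#'
#' @param config a [sim_config()] giving the study design; replicate `r`
#'   uses a seed derived from `config$seed` and `r`.
#' @param n_replicates number of simulated studies (>= 2).
#' @param params generative truth ([true_params()]).
#' @param priors,mcmc passed to [fit_fgcm()].
#' @return A tibble with one row per coefficient: `term`, `truth`
#'   (analysis scale, averaged over replicates), `bias`, `rmse`,
#'   `coverage_95`, `sign_agreement`, `n_replicates`.
#' @export
recovery_experiment <- function(config, n_replicates,
                                params = true_params(),
                                priors = prior_spec(),
                                mcmc = mcmc_config(n_iterations = 5000,
                                                   n_burnin = 500)) {
  if (!is_count(n_replicates) || n_replicates < 2) {
    abort_config("n_replicates must be a whole number >= 2")
  }
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- substream_seed(config$seed, paste0("replicate", r))
    study <- simulate_study(cfg, params)
    truth <- attr(study$samples, "analysis_scale_truth")
    truth_vec <- c(alpha = truth$alpha,
                   stats::setNames(truth$beta,
                                   paste0("beta", seq_along(truth$beta))),
                   stats::setNames(truth$gamma,
                                   paste0("gamma", seq_along(truth$gamma))))
    kept <- remove_outliers(study$samples)$kept
    inputs <- build_design(kept, study$individuals,
                           include_fec = length(params$gamma) == 9)
    mc <- mcmc
    mc$seed <- substream_seed(cfg$seed, "fit")
    fit <- fit_fgcm(inputs, priors = priors, mcmc = mc)
    est <- tidy(fit)
    est <- est[est$term %in% names(truth_vec), ]
    est$truth <- truth_vec[est$term]
    est$replicate <- r
    est
  })
  dplyr::bind_rows(reps) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      truth = mean(.data$truth),
      bias = mean(.data$estimate - .data$truth),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      coverage_95 = mean(.data$conf.low <= .data$truth &
                           .data$truth <= .data$conf.high),
      sign_agreement = mean(sign(.data$estimate) == sign(.data$truth)),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}
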