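# Synthetic study generator: individuals, seasonal NDVI covariates,
# longitudinal dung samples, and planted outliers.

# Discrete covariate weights used by simulate_individuals(). Caregivers
# (multiparous females in the core group, 0-4) skew low because poaching
# removed many adults; age mates (group members within 4 years of age, 0-8)
# decay more gently.
caregiver_probs <- c(0.35, 0.30, 0.18, 0.11, 0.06)
agemate_probs <- c(0.18, 0.20, 0.16, 0.13, 0.11, 0.08, 0.06, 0.05, 0.03)

#' Simulate the individual table of a longitudinal fGCM study
#'
#' Draws time-invariant, individual-level covariates for `n_individuals`
#' female elephants: the number of adult caregivers `f` (0-4, weighted
#' toward low counts), the number of age mates `m` (0-8), orphan status
#' `o`, non-natal group membership `a` (set only on orphans, since leaving
#' the natal group follows orphaning in this system), age at study start,
#' and for orphans the years already elapsed since the mother's death.
#'
#' @param config a [sim_config()].
#' @return A tibble with one row per individual: `individual_id`, `f`, `m`,
#'   `o`, `a`, `age0_years`, `b0_years` (0 for nonorphans). Deterministic
#'   given `config$seed`.
#' @export
#' @examples
#' ind <- simulate_individuals(sim_config(seed = 7))
#' sum(ind$o); sum(ind$a)
simulate_individuals <- function(config) {
  config <- validate_sim_config(config)
  n <- config$n_individuals
  with_substream(config$seed, "individuals", {
    o <- c(rep(1L, config$n_orphans), rep(0L, n - config$n_orphans))
    a <- integer(n)
    if (config$n_non_natal > 0) a[seq_len(config$n_non_natal)] <- 1L
    age0 <- stats::runif(n, config$age_range_years[1],
                         config$age_range_years[2])
    b0 <- ifelse(o == 1L,
                 stats::runif(n, 1, pmin(age0 - 1, 12)),
                 0)
    tibble::tibble(
      individual_id = sprintf("EL%02d", seq_len(n)),
      f = sample(0:4, n, replace = TRUE, prob = caregiver_probs),
      m = sample(0:8, n, replace = TRUE, prob = agemate_probs),
      o = o,
      a = a,
      age0_years = age0,
      b0_years = b0
    )
  })
}

#' Simulate a daily seasonal NDVI series
#'
#' Emulates the bimodal phenology of a semi-arid East African savanna with
#' two wet seasons per year: the spatial-mean NDVI (`ndvi_mean`, a 0-1
#' greenness index tracking food availability) rises in two smooth peaks
#' per 365-day cycle, and the spatial SD of NDVI (`ndvi_sd`, resource
#' patchiness) is elevated during green-up and dry-down transitions, i.e.
#' proportional to the absolute rate of change of the mean, plus small
#' noise. Both series are strictly positive.
#'
#' @param config a [sim_config()]; `study_length_days` must be >= 30.
#' @return A tibble with `day` (1-based), `ndvi_mean`, `ndvi_sd`.
#'   Deterministic given `config$seed`.
#' @export
simulate_seasonal_covariates <- function(config) {
  config <- validate_sim_config(config)
  if (config$study_length_days < 30) {
    abort_config("study_length_days must be >= 30 for a seasonal series")
  }
  days <- seq_len(config$study_length_days)
  # dominant semiannual harmonic (two green-ups per year, peaks near early
  # May and mid November) amplitude-modulated by a weaker annual one; a
  # harmonic base has curvature everywhere, so smoothing recovers exactly
  # two maxima per cycle
  doy <- ((days - 1) %% 365) + 1
  base <- 0.42 + 0.05 * cos(2 * pi * (doy - 240) / 365) +
    0.15 * cos(4 * pi * (doy - 130) / 365)
  slope <- c(0, diff(base)) # per-day rate of change of the smooth mean
  with_substream(config$seed, "seasonal", {
    ndvi_mean <- pmax(base + stats::rnorm(length(days), 0, 0.001), 1e-3)
    ndvi_sd <- pmax(0.03 + 6 * abs(slope) +
                      stats::rnorm(length(days), 0, 0.002), 1e-3)
    tibble::tibble(day = days, ndvi_mean = ndvi_mean, ndvi_sd = ndvi_sd)
  })
}

# Generator-internal standardization: constant columns contribute nothing
# (zeros) instead of erroring, so degenerate configs (e.g. no orphans)
# still simulate.
safe_scale <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate longitudinal dung samples with fGCM concentrations
#'
#' For each individual draws a sample count near the configured mean
#' (floored at 2), places collection days at least `min_gap_days` apart
#' inside the study window, fills in the time-varying covariates (age and
#' years-since-mother's-death advance with the calendar; pregnancy and
#' lactation as persistent multi-month episodes; time-of-day fraction;
#' hours the sample sat on the ground; NDVI mean/SD read off the seasonal
#' series; a negative-binomial strongylid fecal egg count `w`), and
#' generates the response from the two-level linear structure
#' \deqn{y^*_{ij} = \alpha + x_i'\beta + \eta_i + z_{ij}'\gamma +
#'   \epsilon_{ij}, \quad \eta_i \sim N(0, \sigma_1^2), \;
#'   \epsilon_{ij} \sim N(0, \sigma_2^2)}
#' with all covariates standardized across the generated study. The
#' standardized response is rescaled to exact zero mean and unit sample SD
#' and mapped to ng/g as `fgcm_target_mean_ngg + fgcm_target_sd_ngg * y`,
#' floored at 1 ng/g, so the realized concentration mean and SD equal the
#' configured targets. Because of that rescaling, the generative
#' coefficients divided by the realized SD of \eqn{y^*} are the exact
#' coefficients on the analysis (re-standardized) scale; both are recorded
#' in the attributes `true_params` and `analysis_scale_truth`, with the
#' divisor in `scale_factor`.
#'
#' @param individuals table from [simulate_individuals()].
#' @param seasonal daily series from [simulate_seasonal_covariates()]; must
#'   cover `study_length_days`.
#' @param params a [true_params()]; `sigma1`/`sigma2` may be zero (noise-free
#'   limit) but not negative. A length-9 `gamma` adds a fecal egg count
#'   effect.
#' @param config a [sim_config()].
#' @return A tibble of sample records: `individual_id`, `sample_id`, `date`
#'   (Date), `y_ngg`, `g`, `l`, `p`, `t`, `s`, `v`, `z`, `b`, `w`, with the
#'   attributes described above. Deterministic given `config$seed`.
#' @export
simulate_samples <- function(individuals, seasonal, params, config) {
  config <- validate_sim_config(config)
  if (nrow(individuals) == 0) abort_config("individuals table is empty")
  if (nrow(seasonal) < config$study_length_days) {
    abort_config("seasonal series shorter than study_length_days")
  }
  if (params$sigma1 < 0 || params$sigma2 < 0) {
    abort_config("sigma1 and sigma2 must be non-negative")
  }
  n_ind <- nrow(individuals)
  origin <- as.Date("2015-04-01")

  with_substream(config$seed, "samples", {
    max_n <- floor((config$study_length_days - 1) / config$min_gap_days) + 1
    n_i <- pmax(2L, pmin(max_n, round(stats::rnorm(
      n_ind, config$samples_per_individual_mean,
      config$samples_per_individual_sd))))

    per_ind <- purrr::map(seq_len(n_ind), function(i) {
      ni <- n_i[i]
      slack <- config$study_length_days - (ni - 1) * config$min_gap_days
      u <- sort(stats::runif(ni, 0, slack))
      day <- 1L + as.integer(floor(u)) +
        (seq_len(ni) - 1L) * config$min_gap_days
      # persistent reproductive episodes: gestation ~22 months, lactation
      # ~24 months, windows may start before the study
      preg <- if (stats::runif(1) < 0.3) {
        st <- stats::runif(1, -500, config$study_length_days)
        as.integer(day >= st & day <= st + 660)
      } else rep(0L, ni)
      lact <- if (stats::runif(1) < 0.45) {
        st <- stats::runif(1, -500, config$study_length_days)
        as.integer(day >= st & day <= st + 730)
      } else rep(0L, ni)
      tibble::tibble(
        individual_id = individuals$individual_id[i],
        day = day,
        g = individuals$age0_years[i] + (day - 1) / 365.25,
        l = lact,
        p = preg,
        t = stats::runif(ni, 0.25, 0.8),
        s = stats::rgamma(ni, shape = 1.5, rate = 1.5),
        b = if (individuals$o[i] == 1L) {
          individuals$b0_years[i] + (day - 1) / 365.25
        } else rep(0, ni),
        w = as.numeric(stats::rnbinom(ni, mu = 800, size = 1.2))
      )
    })
    samples <- dplyr::bind_rows(per_ind)
    samples$v <- seasonal$ndvi_mean[samples$day]
    samples$z <- seasonal$ndvi_sd[samples$day]

    # level-1 design on the standardized scale
    xs <- cbind(
      f = safe_scale(individuals$f),
      m = safe_scale(individuals$m),
      n = safe_scale(as.numeric(n_i)),
      o = safe_scale(individuals$o),
      a = safe_scale(individuals$a)
    )
    z_cols <- c("g", "l", "s", "t", "v", "p", "z", "b")
    if (length(params$gamma) == 9) z_cols <- c(z_cols, "w")
    zs <- vapply(z_cols, function(cl) safe_scale(samples[[cl]]),
                 numeric(nrow(samples)))

    idx <- match(samples$individual_id, individuals$individual_id)
    eta <- stats::rnorm(n_ind, 0, params$sigma1)
    eps <- stats::rnorm(nrow(samples), 0, params$sigma2)
    lp <- params$alpha + drop(xs %*% params$beta)[idx] +
      drop(zs %*% params$gamma)
    y_star <- lp + eta[idx] + eps

    s_y <- stats::sd(y_star)
    y_unit <- if (is.finite(s_y) && s_y > 1e-12) {
      (y_star - mean(y_star)) / s_y
    } else {
      y_star - mean(y_star)
    }
    scale_factor <- if (is.finite(s_y) && s_y > 1e-12) s_y else 1

    out <- tibble::tibble(
      individual_id = samples$individual_id,
      sample_id = sprintf("S%04d", seq_len(nrow(samples))),
      date = origin + samples$day - 1L,
      y_ngg = pmax(1, config$fgcm_target_mean_ngg +
                     config$fgcm_target_sd_ngg * y_unit),
      g = samples$g, l = samples$l, p = samples$p, t = samples$t,
      s = samples$s, v = samples$v, z = samples$z, b = samples$b,
      w = samples$w
    )
    attr(out, "true_params") <- params
    attr(out, "scale_factor") <- scale_factor
    attr(out, "analysis_scale_truth") <- list(
      alpha = params$alpha / scale_factor,
      beta = params$beta / scale_factor,
      gamma = params$gamma / scale_factor,
      sigma1 = params$sigma1 / scale_factor,
      sigma2 = params$sigma2 / scale_factor
    )
    attr(out, "y_star") <- y_star
    attr(out, "lp_var") <- stats::var(lp)
    out
  })
}

#' Plant outlier samples
#'
#' Displaces `outlier_count` samples upward, each in a different
#' individual, by `outlier_magnitude_sd` times that individual's sample SD
#' of fGCM concentration, and flags the displaced rows in a provenance
#' column `outlier_injected`. This provides ground truth for exercising the
#' per-individual 3-SD discard rule of [remove_outliers()]. Note that a
#' displacement inflates the SD the point is later judged against: a point
#' moved by \eqn{k} SDs among \eqn{n} samples is only caught by the 3-SD
#' rule when \eqn{k(1 - 1/n) > 3\sqrt{1 + k^2/n}}, which at \eqn{n = 15}
#' requires \eqn{k > 5.8}; the default magnitude of 8 clears it.
#'
#' @param samples sample table from [simulate_samples()].
#' @param config a [sim_config()]; uses `outlier_count`,
#'   `outlier_magnitude_sd`, `seed`.
#' @return The sample table with `y_ngg` displaced on the flagged rows and
#'   a logical `outlier_injected` column. With `outlier_count = 0` the
#'   data are returned unmodified (all flags `FALSE`).
#' @export
inject_outliers <- function(samples, config) {
  config <- validate_sim_config(config)
  ids <- unique(samples$individual_id)
  if (config$outlier_count > length(ids)) {
    abort_config("outlier_count exceeds the number of distinct individuals")
  }
  out <- samples
  out$outlier_injected <- FALSE
  if (config$outlier_count == 0) return(out)
  with_substream(config$seed, "outliers", {
    # a point displaced by k SDs inflates the SD it is judged against to
    # s*sqrt(1 + k^2/n); it exceeds the 3-SD threshold only when
    # k(1 - 1/n) > 3*sqrt(1 + k^2/n), so plant in individuals whose sample
    # count clears that bound (falling back to the best-sampled ones)
    k <- config$outlier_magnitude_sd
    n_by_id <- as.numeric(table(samples$individual_id)[ids])
    catch_ratio <- (k * (1 - 1 / n_by_id)) / (3 * sqrt(1 + k^2 / n_by_id))
    eligible <- ids[catch_ratio > 1.01]
    if (length(eligible) < config$outlier_count) {
      eligible <- ids[order(-catch_ratio)][seq_len(config$outlier_count)]
    }
    chosen <- sample(eligible, config$outlier_count)
    for (id in chosen) {
      rows <- which(out$individual_id == id)
      m_i <- mean(out$y_ngg[rows])
      s_i <- stats::sd(out$y_ngg[rows])
      # displace the sample nearest its individual's mean, so the realized
      # deviation is k SDs almost exactly
      j <- rows[which.min(abs(out$y_ngg[rows] - m_i))]
      out$y_ngg[j] <- m_i + k * s_i
      out$outlier_injected[j] <- TRUE
    }
  })
  out
}

#' Simulate a complete study
#'
#' Convenience wrapper chaining [simulate_individuals()],
#' [simulate_seasonal_covariates()], [simulate_samples()] and
#' [inject_outliers()].
#'
#' @param config a [sim_config()].
#' @param params a [true_params()].
#' @return A list with `individuals`, `seasonal`, `samples` (outliers
#'   planted), `params`, `config`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(seed = 3))
#' nrow(study$samples)
simulate_study <- function(config = sim_config(), params = true_params()) {
  individuals <- simulate_individuals(config)
  seasonal <- simulate_seasonal_covariates(config)
  clean <- simulate_samples(individuals, seasonal, params, config)
  samples <- inject_outliers(clean, config)
  # displacement happens on the ng/g scale; carry generator attributes over
  for (at in c("true_params", "scale_factor", "analysis_scale_truth")) {
    attr(samples, at) <- attr(clean, at)
  }
  list(individuals = individuals, seasonal = seasonal, samples = samples,
       params = params, config = config)
}

#' Write a simulated study to disk
#'
#' Writes `samples.csv` and `individuals.csv` in the schemas consumed by
#' [read_fgcm_tables()], plus a `true_params.json` sidecar recording the
#' seed, the nominal generative parameters, and the exact analysis-scale
#' truth for recovery tests.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(samples = file.path(dir, "samples.csv"),
             individuals = file.path(dir, "individuals.csv"),
             sidecar = file.path(dir, "true_params.json"))
  readr::write_csv(study$samples, paths[["samples"]])
  readr::write_csv(
    study$individuals[, c("individual_id", "f", "m", "o", "a")],
    paths[["individuals"]]
  )
  truth <- attr(study$samples, "analysis_scale_truth")
  jsonlite::write_json(
    list(seed = study$config$seed,
         nominal = unclass(study$params),
         scale_factor = attr(study$samples, "scale_factor"),
         analysis_scale = truth),
    paths[["sidecar"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
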