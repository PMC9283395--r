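# Preprocessing: CSV ingest and validation, per-individual 3-SD outlier
# discard, standardization, and two-level design assembly.

sample_schema <- c("individual_id", "sample_id", "date", "y_ngg", "g", "l",
                   "p", "t", "s", "v", "z", "b", "w")
individual_schema <- c("individual_id", "f", "m", "o", "a")

#' Read and validate the sample and individual tables
#'
#' Reads the two CSVs of a study (one row per dung sample; one row per
#' elephant), checks the schemas, validates the record invariants
#' (`y_ngg > 0`, `t` in `[0,1)`, `s >= 0`, `b >= 0`, binary `o`/`a`/`l`/`p`,
#' non-natal only on orphans, `w >= 0` when present) and referential
#' integrity (every sample's `individual_id` appears in the individual
#' table). Extra columns — e.g. a `discarded` or `outlier_injected` flag in
#' a deposited dataset — are tolerated and passed through. `w` (fecal egg
#' count) may be missing entirely or per-row.
#'
#' @param samples_path,individuals_path CSV paths.
#' @return A list with tibbles `samples` and `individuals`.
#' @export
read_fgcm_tables <- function(samples_path, individuals_path) {
  for (pt in c(samples_path, individuals_path)) {
    if (!file.exists(pt)) abort_validation(paste("no such file:", pt))
  }
  samples <- readr::read_csv(samples_path, show_col_types = FALSE,
                             progress = FALSE)
  individuals <- readr::read_csv(individuals_path, show_col_types = FALSE,
                                 progress = FALSE)

  miss_s <- setdiff(setdiff(sample_schema, "w"), names(samples))
  if (length(miss_s)) {
    abort_validation(paste("samples file missing column(s):",
                           paste(miss_s, collapse = ", ")))
  }
  miss_i <- setdiff(individual_schema, names(individuals))
  if (length(miss_i)) {
    abort_validation(paste("individuals file missing column(s):",
                           paste(miss_i, collapse = ", ")))
  }
  if (!"w" %in% names(samples)) samples$w <- NA_real_
  if (!inherits(samples$date, "Date")) {
    samples$date <- as.Date(samples$date)
  }

  bad_row <- function(cond) which(!is.na(cond) & !cond)
  offenders <- list(
    "y_ngg must be > 0" = bad_row(samples$y_ngg > 0),
    "t must be in [0,1)" = bad_row(samples$t >= 0 & samples$t < 1),
    "s must be >= 0" = bad_row(samples$s >= 0),
    "b must be >= 0" = bad_row(samples$b >= 0),
    "w must be >= 0" = bad_row(is.na(samples$w) | samples$w >= 0),
    "l must be 0/1" = bad_row(samples$l %in% c(0, 1)),
    "p must be 0/1" = bad_row(samples$p %in% c(0, 1)),
    "date must parse" = which(is.na(samples$date)),
    "y_ngg must parse" = which(is.na(samples$y_ngg))
  )
  offenders <- offenders[lengths(offenders) > 0]
  if (length(offenders)) {
    msgs <- vapply(names(offenders), function(m) {
      sprintf("%s (sample rows %s)", m,
              paste(utils::head(offenders[[m]], 10), collapse = ", "))
    }, character(1))
    abort_validation(paste0("invalid sample rows:\n",
                            paste(msgs, collapse = "\n")))
  }
  iv <- individuals
  bad_i <- unique(c(bad_row(iv$o %in% c(0, 1)), bad_row(iv$a %in% c(0, 1)),
                    bad_row(iv$f >= 0), bad_row(iv$m >= 0),
                    bad_row(iv$a == 0 | iv$o == 1)))
  if (length(bad_i)) {
    abort_validation(paste("invalid individual rows (non-natal requires",
                           "orphan; o/a binary; f,m >= 0):",
                           paste(sort(bad_i), collapse = ", ")))
  }
  unknown <- !samples$individual_id %in% individuals$individual_id
  if (any(unknown)) {
    abort_validation(paste(
      "referential integrity: sample rows reference unknown individual_id:",
      paste(utils::head(which(unknown), 10), collapse = ", ")))
  }
  list(samples = samples, individuals = individuals)
}

#' Discard per-individual 3-SD outliers
#'
#' Applies the discard rule once, per individual, on the raw ng/g scale:
#' a sample is discarded iff its fGCM concentration lies strictly more
#' than three standard deviations from the mean concentration of the
#' individual it came from, where the mean and the sample SD (n-1
#' denominator) are computed from all of that individual's samples
#' including the candidate. A consequence of using the sample SD is that
#' no point can possibly be discarded from an individual with 10 or fewer
#' samples (the largest attainable deviation is \eqn{(n-1)/\sqrt{n}} SDs).
#'
#' @param samples a sample table (must have `individual_id`, `y_ngg`).
#' @return A list with `kept` and `discarded` tibbles; together they
#'   partition the input with original row order preserved.
#' @export
#' @examples
#' x <- tibble::tibble(individual_id = "A",
#'                     y_ngg = c(rep(100, 14), 1000))
#' remove_outliers(x)$discarded$y_ngg
remove_outliers <- function(samples) {
  counts <- table(samples$individual_id)
  singletons <- names(counts)[counts < 2]
  if (length(singletons)) {
    abort_validation(paste(
      "outlier rule needs >= 2 samples per individual; individual(s)",
      paste(singletons, collapse = ", "), "have fewer"))
  }
  grp <- samples$individual_id
  mean_i <- stats::ave(samples$y_ngg, grp, FUN = mean)
  sd_i <- stats::ave(samples$y_ngg, grp, FUN = stats::sd)
  drop <- abs(samples$y_ngg - mean_i) > 3 * sd_i
  drop[is.na(drop)] <- FALSE # zero-SD individuals: nothing to discard
  list(kept = samples[!drop, , drop = FALSE],
       discarded = samples[drop, , drop = FALSE])
}

#' Standardize a numeric vector to z-scores
#'
#' Subtracts the mean and divides by the sample SD (n-1 denominator).
#'
#' @param x numeric vector, length >= 2, non-constant, no missing values.
#' @param name column name used in error messages.
#' @return A list with `values` (mean 0, SD 1), `mean`, `sd`; the returned
#'   moments invert the transform exactly.
#' @export
#' @examples
#' standardize(1:5)$values
standardize <- function(x, name = deparse(substitute(x))) {
  if (length(x) < 2) {
    abort_validation(sprintf("column `%s`: need >= 2 values", name))
  }
  if (anyNA(x)) {
    abort_validation(sprintf("column `%s`: missing values", name))
  }
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    abort_validation(sprintf(
      "column `%s` is constant and cannot be standardized (unidentifiable)",
      name))
  }
  list(values = (x - m) / s, mean = m, sd = s)
}

#' Standardize columns of a data frame
#'
#' @param data a data frame.
#' @param cols character vector of column names to standardize.
#' @return `data` with the named columns replaced by z-scores; the
#'   attribute `"standardization"` holds a tibble (`column`, `mean`, `sd`).
#' @export
standardize_columns <- function(data, cols) {
  params <- purrr::map(cols, function(cl) {
    st <- standardize(data[[cl]], name = cl)
    data[[cl]] <<- st$values
    tibble::tibble(column = cl, mean = st$mean, sd = st$sd)
  })
  attr(data, "standardization") <- dplyr::bind_rows(params)
  data
}

#' Assemble the two-level model inputs
#'
#' From an outlier-filtered sample table and the individual table, builds
#' the standardized design of the two-level hierarchical model:
#' * level 1 (between individuals): covariates `f` (caregivers), `m` (age
#'   mates), `n` (number of retained samples, recomputed here), `o`
#'   (orphan), `a` (non-natal), standardized across individuals, and the
#'   per-individual mean `ybar` of the standardized response;
#' * level 2 (within individuals): covariates `g` (age), `l` (lactating),
#'   `s` (hours on ground), `t` (time-of-day fraction), `v` (mean NDVI),
#'   `p` (pregnant), `z` (NDVI spatial SD), `b` (years since mother's
#'   death) and, with `include_fec = TRUE`, `w` (strongylid eggs/g),
#'   standardized across samples, plus the standardized response `y`.
#'
#' All columns — binaries included — are standardized, so fitted
#' coefficients are in SD units throughout. With `include_fec = TRUE`,
#' rows with missing `w` are dropped first and everything (response
#' included) is re-standardized on the remaining subset; individuals left
#' with no samples are dropped from level 1. Rows are put in a canonical
#' order (individuals by id; samples by id, date, sample id) so identical
#' data yield bit-identical designs regardless of input row order.
#'
#' @param samples the `kept` table from [remove_outliers()].
#' @param individuals the individual table.
#' @param include_fec add the fecal-egg-count column `w` as a ninth
#'   level-2 covariate?
#' @return An object of class `fgcm_model_inputs`: list with
#'   `individual_index`, `X` (I x 5), `ybar`, `sample_index`, `Z`
#'   (N x 8 or 9), `y`, `standardization` (tibble incl. the response
#'   `y_ngg`).
#' @export
build_design <- function(samples, individuals, include_fec = FALSE) {
  stopifnot(all(c("individual_id", "y_ngg") %in% names(samples)))
  if (include_fec) {
    keep <- !is.na(samples$w)
    if (!any(keep)) {
      abort_validation("include_fec = TRUE but no non-missing w values")
    }
    samples <- samples[keep, , drop = FALSE]
  } else {
    samples <- samples[, setdiff(names(samples), "w"), drop = FALSE]
  }
  individuals <- individuals[individuals$individual_id %in%
                               samples$individual_id, , drop = FALSE]
  individuals <- individuals[order(individuals$individual_id), , drop = FALSE]
  ord <- order(samples$individual_id, samples$date, samples$sample_id)
  samples <- samples[ord, , drop = FALSE]

  # n_i: retained samples per individual, recomputed post-filter
  n_i <- as.numeric(table(samples$individual_id)[individuals$individual_id])

  x_raw <- tibble::tibble(
    f = as.numeric(individuals$f), m = as.numeric(individuals$m),
    n = n_i, o = as.numeric(individuals$o), a = as.numeric(individuals$a))
  z_cols <- c("g", "l", "s", "t", "v", "p", "z", "b")
  if (include_fec) z_cols <- c(z_cols, "w")
  z_raw <- tibble::as_tibble(lapply(
    stats::setNames(z_cols, z_cols),
    function(cl) as.numeric(samples[[cl]])))

  x_std <- standardize_columns(x_raw, names(x_raw))
  z_std <- standardize_columns(z_raw, names(z_raw))
  y_std <- standardize(samples$y_ngg, name = "y_ngg")

  sample_index <- match(samples$individual_id, individuals$individual_id)
  y <- y_std$values
  ybar <- as.numeric(tapply(y, sample_index, mean))

  std <- dplyr::bind_rows(
    attr(x_std, "standardization"),
    attr(z_std, "standardization"),
    tibble::tibble(column = "y_ngg", mean = y_std$mean, sd = y_std$sd))

  structure(list(
    individual_index = individuals$individual_id,
    X = as.matrix(x_std),
    ybar = ybar,
    sample_index = sample_index,
    sample_id = samples$sample_id,
    Z = as.matrix(z_std),
    y = y,
    standardization = std
  ), class = "fgcm_model_inputs")
}

#' @export
print.fgcm_model_inputs <- function(x, ...) {
  cat(sprintf(
    "<fgcm_model_inputs> %d individuals x %d level-1 covariates; %d samples x %d level-2 covariates\n",
    nrow(x$X), ncol(x$X), nrow(x$Z), ncol(x$Z)))
  invisible(x)
}
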