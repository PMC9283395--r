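# Internal helpers: seed sub-streams, validation, small numerics.

#' Derive a deterministic sub-stream seed
#'
#' All randomness in the package flows from one root seed; each operation
#' draws from its own sub-stream so that, e.g., adding samples does not
#' perturb the individual table. The derivation is a simple 32-bit mix of
#' the root seed and an operation label.
#'
#' @param seed integer root seed.
#' @param label character label of the operation (e.g. "individuals").
#' @return An integer seed in [0, 2^31 - 2].
#' @keywords internal
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Run code under a local seed without disturbing the caller's RNG state.
with_substream <- function(seed, label, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  force(code)
}

abort_config <- function(msg) {
  rlang::abort(msg, class = "fgcmhier_config_error")
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "fgcmhier_validation_error")
}

# Check that a scalar is a non-negative whole number.
is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x
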