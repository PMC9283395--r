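# Convergence diagnostics and posterior predictive model checks.

#' Gelman-Rubin corrected potential scale reduction factor (Rc)
#'
#' Computes the corrected (degrees-of-freedom adjusted) potential scale
#' reduction factor on unsplit chains: with m chains of length n,
#' within-chain variance W (mean of per-chain variances), between-chain
#' variance B (n times the variance of chain means), the pooled posterior
#' variance estimate is `sigma2 = ((n - 1)/n) W + B/n`, inflated by
#' sampling variability of the chain means to `V = sigma2 + B/(m n)`, and
#' `Rc = sqrt(((d + 3)/(d + 1)) * V / W)` where `d` is a method-of-moments
#' estimate of the degrees of freedom of the t-approximation to the pooled
#' estimate. Values near 1 indicate the chains have mixed; > 1.1 is the
#' conventional alarm threshold.
#'
#' @param chains a list of >= 2 numeric vectors (one per chain, equal
#'   length >= 10), or a matrix with one column per chain.
#' @return The Rc point estimate (scalar). Identical chains return exactly
#'   1; chains that are all constant but unequal are an error.
#' @export
#' @examples
#' set.seed(1)
#' gelman_rubin(list(rnorm(500), rnorm(500)))
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  m <- length(chains)
  if (m < 2) abort_validation("gelman_rubin needs >= 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) abort_validation("chains must have equal length")
  if (n < 10) abort_validation("chains must have length >= 10")
  cmat <- do.call(cbind, chains)

  xbar <- colMeans(cmat)
  s2 <- apply(cmat, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(xbar)
  if (W == 0) {
    if (B == 0) return(1)
    abort_validation(
      "all chains constant but unequal: Rc undefined (W = 0, B > 0)")
  }
  sigma2 <- (n - 1) / n * W + B / n
  V <- sigma2 + B / (m * n)

  # df of the t-approximation, via the estimated variance of V
  muhat <- mean(xbar)
  var_w <- stats::var(s2) / m
  var_b <- 2 * B^2 / (m - 1)
  cov_wb <- (n / m) * (stats::cov(s2, xbar^2) -
                         2 * muhat * stats::cov(s2, xbar))
  var_V <- ((n - 1) / n)^2 * var_w + ((m + 1) / (m * n))^2 * var_b +
    2 * ((m + 1) * (n - 1) / (m * n^2)) * cov_wb
  d <- 2 * V^2 / var_V
  correction <- if (is.finite(d) && d > 0) (d + 3) / (d + 1) else 1
  sqrt(correction * V / W)
}

#' Per-parameter convergence report
#'
#' Applies [gelman_rubin()] to every parameter of a fitted model.
#'
#' @param fit an `fgcm_fit` with >= 2 chains.
#' @param threshold convergence threshold on Rc (default 1.1).
#' @return A tibble with `term`, `rhat`, `converged`, and the threshold as
#'   attribute `"threshold"`.
#' @export
convergence_report <- function(fit, threshold = 1.1) {
  if (length(fit$draws) < 2) {
    abort_validation("convergence diagnostics need >= 2 chains")
  }
  rhat <- vapply(seq_along(fit$parameters), function(j) {
    gelman_rubin(lapply(fit$draws, function(ch) ch[, j]))
  }, numeric(1))
  out <- tibble::tibble(term = fit$parameters, rhat = rhat,
                        converged = rhat < threshold)
  attr(out, "threshold") <- threshold
  out
}

#' Posterior predictive checks (Bayesian p-values)
#'
#' For each retained posterior draw, replicates both model levels'
#' data — `ybar_rep ~ Normal(mu_i, 1/tau1)` per individual and
#' `y_rep ~ Normal(mu_ij, 1/tau2)` per sample — and compares the mean and
#' SD of each replicated vector with those of the observed data. Each
#' Bayesian p-value is the proportion of draws whose replicated statistic
#' is greater than or equal to the observed one; values near 0 or 1 flag
#' systematic misfit, values near 0.5 are ideal.
#'
#' @param fit an `fgcm_fit`.
#' @param inputs model inputs; defaults to those stored in the fit and
#'   must match its dimensions.
#' @param seed integer seed for the replication noise.
#' @param n_draws optional subsample of retained draws to use (default:
#'   all).
#' @return An object of class `fgcm_ppc`: tibble with columns `level`
#'   (1 or 2), `statistic` (`"mean"`/`"sd"`), `observed`, `p_value`, and
#'   attribute `n_draws_used`.
#' @export
posterior_predictive_check <- function(fit, inputs = fit$inputs,
                                       seed = fit$mcmc$seed,
                                       n_draws = NULL) {
  check_inputs(inputs)
  draws <- pooled_draws(fit)
  if (nrow(draws) == 0) abort_validation("no retained draws")
  sd_ <- stack_designs(inputs)
  if (!identical(colnames(draws),
                 c(sd_$names, "tau1", "tau2"))) {
    abort_validation("draws and inputs have mismatched parameters")
  }
  if (!is.null(n_draws) && n_draws < nrow(draws)) {
    pick <- with_substream(seed, "ppc_subsample",
                           sample.int(nrow(draws), n_draws))
    draws <- draws[sort(pick), , drop = FALSE]
  }
  S <- nrow(draws)
  theta <- draws[, sd_$names, drop = FALSE]
  # floor precisions so prior-predictive draws (which can be numerically
  # zero under a diffuse gamma prior) yield huge-but-finite replicate noise
  tau1 <- pmax(draws[, "tau1"], 1e-300)
  tau2 <- pmax(draws[, "tau2"], 1e-300)

  obs <- c(mean1 = mean(inputs$ybar), sd1 = stats::sd(inputs$ybar),
           mean2 = mean(inputs$y), sd2 = stats::sd(inputs$y))

  ge <- matrix(0L, S, 4) # indicator T(rep) >= T(obs), draws x statistic
  with_substream(seed, "ppc", {
    block <- max(1L, floor(2e6 / (sd_$I + sd_$N)))
    for (st in seq(1, S, by = block)) {
      en <- min(S, st + block - 1)
      idx <- st:en
      mu1 <- sd_$A %*% t(theta[idx, , drop = FALSE]) # I x s
      mu2 <- sd_$B %*% t(theta[idx, , drop = FALSE]) # N x s
      s <- length(idx)
      rep1 <- mu1 + matrix(stats::rnorm(sd_$I * s), sd_$I, s) *
        rep(1 / sqrt(tau1[idx]), each = sd_$I)
      rep2 <- mu2 + matrix(stats::rnorm(sd_$N * s), sd_$N, s) *
        rep(1 / sqrt(tau2[idx]), each = sd_$N)
      ge[idx, 1] <- colMeans(rep1) >= obs["mean1"]
      ge[idx, 2] <- apply(rep1, 2, stats::sd) >= obs["sd1"]
      ge[idx, 3] <- colMeans(rep2) >= obs["mean2"]
      ge[idx, 4] <- apply(rep2, 2, stats::sd) >= obs["sd2"]
    }
  })
  out <- tibble::tibble(
    level = c(1L, 1L, 2L, 2L),
    statistic = c("mean", "sd", "mean", "sd"),
    observed = unname(obs),
    p_value = colMeans(ge)
  )
  attr(out, "n_draws_used") <- S
  class(out) <- c("fgcm_ppc", class(out))
  out
}
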