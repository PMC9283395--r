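# Two-level model: log posterior oracle checks, Gibbs sampler equivalences,
# posterior summaries.

test_that("log_posterior matches the closed form at unit precision", {
  inp <- manual_inputs(I = 4, N = 9)
  inp$ybar <- inp$ybar - mean(inp$ybar)
  inp$y <- inp$y - mean(inp$y)
  pr <- prior_spec()
  state <- list(alpha = 0, beta = 0, gamma = 0, tau1 = 1, tau2 = 1)
  lp <- log_posterior(state, inp, pr)
  prior_term <- sum(dnorm(c(0, 0, 0), 0, 1000, log = TRUE)) +
    2 * dgamma(1, 0.001, rate = 0.001, log = TRUE)
  expected <- -4 / 2 * log(2 * pi) - sum(inp$ybar^2) / 2 -
    9 / 2 * log(2 * pi) - sum(inp$y^2) / 2 + prior_term
  expect_equal(lp, expected, tolerance = 1e-12)

  expect_identical(log_posterior(list(alpha = 0, beta = 0, gamma = 0,
                                      tau1 = 1, tau2 = 0), inp, pr), -Inf)
})

test_that("log_posterior agrees with term-by-term scalar summation", {
  inp <- manual_inputs(I = 3, N = 7)
  pr <- prior_spec(coef_prior_sd = 3, precision_shape = 2,
                   precision_rate = 1.5)
  state <- list(alpha = 0.4, beta = -0.8, gamma = 1.1,
                tau1 = 0.7, tau2 = 2.2)
  # independent oracle: write out every scalar normal log-density
  logn <- function(x, mu, var) -0.5 * log(2 * pi * var) - (x - mu)^2 / (2 * var)
  mu_i <- state$alpha + inp$X[, 1] * state$beta
  mu_ij <- mu_i[inp$sample_index] + inp$Z[, 1] * state$gamma
  oracle <- 0
  for (i in 1:3) oracle <- oracle + logn(inp$ybar[i], mu_i[i], 1 / state$tau1)
  for (j in 1:7) oracle <- oracle + logn(inp$y[j], mu_ij[j], 1 / state$tau2)
  for (cc in c(state$alpha, state$beta, state$gamma)) {
    oracle <- oracle + logn(cc, 0, 9)
  }
  oracle <- oracle +
    dgamma(state$tau1, 2, rate = 1.5, log = TRUE) +
    dgamma(state$tau2, 2, rate = 1.5, log = TRUE)
  expect_equal(log_posterior(state, inp, pr), oracle, tolerance = 1e-10)
})

test_that("intercept-only posterior matches the conjugate normal formula", {
  set.seed(42)
  I <- 6; N <- 24
  idx <- rep(1:I, each = 4)
  y <- rnorm(N, 2, 1)
  ybar <- as.numeric(tapply(y, idx, mean))
  inp <- structure(list(individual_index = as.character(1:I),
                        X = matrix(numeric(0), I, 0), ybar = ybar,
                        sample_index = idx,
                        Z = matrix(numeric(0), N, 0), y = y,
                        standardization = NULL),
                   class = "fgcm_model_inputs")
  # precisions pinned at 1 by a sharply concentrated prior; flat-ish
  # coefficient prior
  pr <- prior_spec(coef_prior_sd = 1000,
                   precision_shape = 1e8, precision_rate = 1e8)
  fit <- fit_fgcm(inp, priors = pr,
                  mcmc = fast_mcmc(seed = 5, n_iterations = 6000,
                                   n_burnin = 1000))
  draws <- do.call(rbind, fit$draws)[, "alpha"]
  prec <- I + N + 1e-6
  post_mean <- (sum(ybar) + sum(y)) / prec
  post_sd <- 1 / sqrt(prec)
  mcse <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - post_mean), 3 * mcse + 1e-8)
  expect_lt(abs(sd(draws) - post_sd) / post_sd, 0.05)
})

test_that("sampler matches the paper's engine on a shared instance", {
  inputs <- small_inputs(seed = 20)
  fit <- fit_fgcm(inputs, mcmc = fast_mcmc(seed = 31, n_chains = 3,
                                           n_iterations = 6000,
                                           n_burnin = 1000))
  td <- tidy(fit)

  model_string <- "
    model {
      for (i in 1:I) {
        ybar[i] ~ dnorm(mu1[i], tau1)
        mu1[i] <- alpha + inprod(X[i, ], beta)
      }
      for (j in 1:N) {
        y[j] ~ dnorm(mu2[j], tau2)
        mu2[j] <- mu1[ind[j]] + inprod(Z[j, ], gamma)
      }
      alpha ~ dnorm(0, 1e-6)
      for (k in 1:5) { beta[k] ~ dnorm(0, 1e-6) }
      for (k in 1:8) { gamma[k] ~ dnorm(0, 1e-6) }
      tau1 ~ dgamma(0.001, 0.001)
      tau2 ~ dgamma(0.001, 0.001)
    }"
  jm <- rjags::jags.model(
    textConnection(model_string),
    data = list(I = nrow(inputs$X), N = nrow(inputs$Z), X = inputs$X,
                Z = inputs$Z, ybar = inputs$ybar, y = inputs$y,
                ind = inputs$sample_index),
    n.chains = 2, quiet = TRUE,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 7))
  update(jm, 2000, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("alpha", "beta", "gamma", "tau1", "tau2"),
                            n.iter = 8000, progress.bar = "none")
  jdraws <- do.call(rbind, lapply(js, as.matrix))
  jmean <- colMeans(jdraws)
  names(jmean) <- sub("\\[(\\d)\\]", "\\1", names(jmean))
  for (tm in td$term) {
    expect_lt(abs(td$estimate[td$term == tm] - jmean[[tm]]),
              0.02 + 0.05 * abs(jmean[[tm]]))
  }
})

test_that("collinear designs fail loudly, naming columns", {
  inp <- small_inputs(seed = 22)
  inp$Z <- cbind(inp$Z, dup = inp$Z[, "g"])
  expect_error(fit_fgcm(inp, mcmc = fast_mcmc()), "collinear.*\\(dup\\)")
  expect_error(mcmc_config(n_iterations = 1000, n_burnin = 1000),
               "retained")
})

test_that("with no data the posterior reproduces the prior", {
  inp <- structure(list(individual_index = character(0),
                        X = matrix(numeric(0), 0, 0), ybar = numeric(0),
                        sample_index = integer(0),
                        Z = matrix(numeric(0), 0, 0), y = numeric(0),
                        standardization = NULL),
                   class = "fgcm_model_inputs")
  pr <- prior_spec(coef_prior_sd = 2, precision_shape = 3,
                   precision_rate = 2)
  fit <- fit_fgcm(inp, priors = pr,
                  mcmc = fast_mcmc(seed = 8, n_iterations = 16000,
                                   n_burnin = 1000))
  draws <- do.call(rbind, fit$draws)
  expect_lt(abs(mean(draws[, "alpha"])), 3 * 2 / sqrt(nrow(draws)) * 1.5)
  expect_lt(abs(sd(draws[, "alpha"]) - 2) / 2, 0.05)
  expect_lt(abs(mean(draws[, "tau1"]) - 3 / 2), 0.05)
  expect_lt(abs(sd(draws[, "tau2"]) - sqrt(3) / 2), 0.05)
})

test_that("fits are chain-seeded, deterministic, and order-invariant", {
  study <- simulate_study(small_config(seed = 23))
  kept <- remove_outliers(study$samples)$kept
  a <- fit_fgcm(build_design(kept, study$individuals),
                mcmc = fast_mcmc(seed = 11, n_iterations = 1500))
  perm <- kept[rev(seq_len(nrow(kept))), ]
  b <- fit_fgcm(build_design(perm, study$individuals),
                mcmc = fast_mcmc(seed = 11, n_iterations = 1500))
  expect_identical(a$draws, b$draws)
  c2 <- fit_fgcm(build_design(kept, study$individuals),
                 mcmc = fast_mcmc(seed = 12, n_iterations = 1500))
  expect_false(identical(a$draws[[1]], c2$draws[[1]]))
  # chains differ from one another but share the posterior
  expect_false(identical(a$draws[[1]], a$draws[[2]]))
})

test_that("unstandardized inputs are refused", {
  inp <- small_inputs(seed = 24)
  inp$X[, 1] <- inp$X[, 1] * 3 + 2
  expect_error(fit_fgcm(inp, mcmc = fast_mcmc()), "standardized")
})

test_that("tidy summaries: quantile nesting, flags, ordering", {
  inp <- manual_inputs()
  const <- matrix(2, 600, 1, dimnames = list(NULL, "alpha"))
  fitc <- manual_fit(list(const, const), inp)
  tdc <- tidy(fitc)
  expect_equal(tdc$estimate, 2)
  expect_equal(tdc$conf.low, 2)
  expect_equal(tdc$conf.high.50, 2)
  expect_true(tdc$excludes_zero_95)

  set.seed(1)
  z <- matrix(rnorm(1e5), ncol = 1, dimnames = list(NULL, "gamma1"))
  fitz <- manual_fit(list(z), inp)
  tdz <- tidy(fitz)
  expect_lt(abs(tdz$conf.low - (-1.96)), 0.05)
  expect_lt(abs(tdz$conf.high - 1.96), 0.05)
  expect_false(tdz$excludes_zero_95)
  expect_true(tdz$conf.low <= tdz$conf.low.50 &
                tdz$conf.low.50 <= tdz$conf.high.50 &
                tdz$conf.high.50 <= tdz$conf.high)

  fit <- fit_fgcm(small_inputs(seed = 25), mcmc = fast_mcmc(seed = 2))
  td <- tidy(fit)
  for (lv in c("level1", "level2")) {
    expect_false(is.unsorted(td$estimate[td$level == lv]))
  }
  gl <- glance(fit)
  expect_equal(gl$n_chains, 2)
  expect_true(is.finite(gl$max_rhat))
})
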