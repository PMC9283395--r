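# Shared fixtures: all built in code at test time.

# A small hand-sized study for fast model tests.
small_config <- function(seed = 1, ...) {
  sim_config(n_individuals = 12, n_orphans = 8, n_non_natal = 2,
             samples_per_individual_mean = 8, samples_per_individual_sd = 2,
             study_length_days = 200, outlier_count = 0, seed = seed, ...)
}

small_inputs <- function(seed = 1, params = true_params()) {
  st <- simulate_study(small_config(seed), params)
  build_design(remove_outliers(st$samples)$kept, st$individuals)
}

fast_mcmc <- function(seed = 1, n_chains = 2, n_iterations = 3000,
                      n_burnin = 500) {
  mcmc_config(n_chains = n_chains, n_iterations = n_iterations,
              n_burnin = n_burnin, seed = seed)
}

# Minimal hand-built model inputs (already standardized covariates).
manual_inputs <- function(I = 3, N = 7, kx = 1, kz = 1, seed = 99) {
  set.seed(seed)
  X <- matrix(rnorm(I * kx), I, kx)
  X <- apply(X, 2, function(c) (c - mean(c)) / sd(c))
  X <- matrix(X, I, kx, dimnames = list(NULL, paste0("x", seq_len(kx))))
  idx <- sort(rep_len(seq_len(I), N))
  Z <- matrix(rnorm(N * kz), N, kz)
  Z <- apply(Z, 2, function(c) (c - mean(c)) / sd(c))
  Z <- matrix(Z, N, kz, dimnames = list(NULL, paste0("z", seq_len(kz))))
  y <- rnorm(N, 1.5 + X[idx, 1] + Z[, 1], 0.7)
  ybar <- as.numeric(tapply(y, idx, mean))
  structure(list(individual_index = paste0("I", seq_len(I)), X = X,
                 ybar = ybar, sample_index = idx, Z = Z, y = y,
                 standardization = NULL),
            class = "fgcm_model_inputs")
}

# Assemble an fgcm_fit by hand from given per-chain draw matrices.
manual_fit <- function(chains, inputs) {
  structure(list(draws = chains, parameters = colnames(chains[[1]]),
                 inputs = inputs, priors = prior_spec(),
                 mcmc = mcmc_config(n_chains = length(chains),
                                    n_iterations = nrow(chains[[1]]) + 2,
                                    n_burnin = 1, seed = 1)),
            class = "fgcm_fit")
}
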