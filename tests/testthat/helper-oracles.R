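# Independent oracles and shared fixtures for the test suite.

# Dense-matrix bivariate normal log-likelihood: generic inverse/determinant
# route, independent of the closed-form 2x2 expression in mv_loglik().
mv_loglik_dense <- function(params, data) {
  s1 <- params$sigma1; s2 <- params$sigma2; rho <- params$rho
  Sigma <- matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2, 2)
  Sinv <- solve(Sigma)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  mu <- c(params$F1^2, params$F2^2)
  tot <- 0
  for (i in seq_len(data$n)) {
    r <- c(data$I1[i], data$I2[i]) - mu
    tot <- tot - log(2 * pi) - ld / 2 - drop(t(r) %*% Sinv %*% r) / 2
  }
  tot
}

# Brute-force HDI: scan every contiguous window of the sorted sample.
hdi_bruteforce <- function(samples, mass = 0.95) {
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in 1:(n - k + 1)) {
    lo <- x[i]; hi <- x[i + k - 1]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# Random valid multivariate parameter states for oracle comparisons.
random_mv_params <- function() {
  mv_params(F1 = runif(1, 0, 3), F2 = runif(1, 0, 3),
            sigma1 = runif(1, 0.2, 3), sigma2 = runif(1, 0.2, 3),
            rho = runif(1, -0.9, 0.9))
}

random_pairs <- function(n = 20) {
  intensity_pairs(rnorm(n, 1, 2), rnorm(n, 1, 2))
}

# Short chain protocol for tests that only need a working posterior, not
# the full reference protocol.
quick_chain <- function(seed = 1, n_chains = 1) {
  chain_config(n_iter = 6000, burn_in = 2000, seed = seed,
               n_chains = n_chains)
}

# The five generative settings of the model-comparison study (each row:
# F1_true, F2_true, mu_sys, sigma_sys, sigma_ran at 200 pairs).
study_grid <- function(n_pairs = 200) {
  data.frame(
    F1_true   = c(0.1, 0.2, 1.0, 3.0, 0.6),
    F2_true   = c(0.7, 0.5, 0.1, 0.5, 0.1),
    mu_sys    = c(-0.5, -1.0, 0.0, -5.0, -0.5),
    sigma_sys = c(1.5, 1.5, 2.0, 6.0, 1.2),
    sigma_ran = c(0.3, 0.3, 1.0, 3.0, 0.4),
    n_pairs   = n_pairs
  )
}
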