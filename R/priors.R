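#' Prior configuration for the amplitude models
#'
#' Bundles the prior choices used by both Bayesian models: the amplitude
#' prior on F1 and F2 (uniform on `[0, upper]`, or a normal truncated to
#' `F >= 0`), a shared log-normal prior on the likelihood standard
#' deviations sigma1 and sigma2, and the LKJ shape `eta` for the
#' correlation of the bivariate model.
#'
#' Defaults: a flat uniform amplitude prior on (0, 1e8); log-normal
#' hyperparameters `mu_log = 0`, `sigma_log = 1`, weakly informative on the
#' unit intensity scale of commonly scaled data; `lkj_eta = 1`, flat over
#' correlations.
#'
#' @param amplitude one of:
#'   * `list(type = "uniform", upper = U)` — flat on `[0, U]`;
#'   * `list(type = "truncated_normal", mu = m, sigma = s)` — Normal(m, s)
#'     restricted to `F >= 0` and renormalized.
#' @param sigma_mu_log,sigma_sigma_log log-normal hyperparameters for
#'   sigma1 and sigma2 (`sigma_sigma_log > 0`).
#' @param lkj_eta LKJ shape (`> 0`); larger values concentrate the prior of
#'   the correlation around zero, `eta = 1` is flat.
#' @return An object of class `"prior_config"`.
#' @examples
#' prior_config()  # uniform(0, 1e8) amplitudes
#' prior_config(amplitude = list(type = "truncated_normal", mu = 0.7, sigma = 7))
#' @export
prior_config <- function(amplitude = list(type = "uniform", upper = 1e8),
                         sigma_mu_log = 0, sigma_sigma_log = 1,
                         lkj_eta = 1) {
  if (!is.list(amplitude) || is.null(amplitude$type))
    stop("'amplitude' must be a list with a 'type' field", call. = FALSE)
  type <- match.arg(amplitude$type, c("uniform", "truncated_normal"))
  if (type == "uniform") {
    upper <- amplitude$upper
    if (is.null(upper)) upper <- 1e8
    if (!is.numeric(upper) || length(upper) != 1L || !(upper > 0))
      stop("uniform amplitude prior needs 'upper' > 0", call. = FALSE)
    amplitude <- list(type = "uniform", upper = as.numeric(upper))
  } else {
    mu <- amplitude$mu; sigma <- amplitude$sigma
    if (is.null(mu) || is.null(sigma) ||
        !is.numeric(mu) || !is.numeric(sigma) || !(sigma > 0))
      stop("truncated_normal amplitude prior needs 'mu' and 'sigma' > 0",
           call. = FALSE)
    amplitude <- list(type = "truncated_normal",
                      mu = as.numeric(mu), sigma = as.numeric(sigma))
  }
  if (!is.numeric(sigma_sigma_log) || !(sigma_sigma_log > 0))
    stop("'sigma_sigma_log' must be > 0", call. = FALSE)
  if (!is.numeric(lkj_eta) || !(lkj_eta > 0))
    stop("'lkj_eta' must be > 0", call. = FALSE)
  structure(list(amplitude = amplitude,
                 sigma_mu_log = as.numeric(sigma_mu_log),
                 sigma_sigma_log = as.numeric(sigma_sigma_log),
                 lkj_eta = as.numeric(lkj_eta)),
            class = "prior_config")
}

#' @export
print.prior_config <- function(x, ...) {
  cat("Prior configuration\n")
  if (x$amplitude$type == "uniform")
    cat(sprintf("  amplitudes: Uniform(0, %g)\n", x$amplitude$upper))
  else
    cat(sprintf("  amplitudes: Normal(%g, %g) truncated to F >= 0\n",
                x$amplitude$mu, x$amplitude$sigma))
  cat(sprintf("  sigma1, sigma2: logNormal(mu_log = %g, sigma_log = %g)\n",
              x$sigma_mu_log, x$sigma_sigma_log))
  cat(sprintf("  correlation: LKJ(eta = %g)\n", x$lkj_eta))
  invisible(x)
}

#' Log-density of the 2x2 LKJ correlation prior
#'
#' For a 2x2 correlation matrix the LKJ distribution reduces to a density
#' over the single off-diagonal correlation `rho` proportional to
#' `(1 - rho^2)^(eta - 1)` on (-1, 1).  The value returned here is
#' normalized: the log-normalizer of the 2x2 case is
#' `-(2*eta - 1) * log(2) - lbeta(eta, eta)`.  At `eta = 1` the prior is
#' flat (density 1/2); as `eta` grows it concentrates around `rho = 0`,
#' i.e. around the unit correlation matrix.
#'
#' Out-of-support `rho` (|rho| >= 1) returns `-Inf` rather than raising, so
#' a Metropolis sampler can reject such proposals uniformly.
#'
#' @param rho correlation value(s).
#' @param eta LKJ shape, `> 0`.
#' @return Normalized log-density, vectorized over `rho`.
#' @export
lkj_logpdf_2x2 <- function(rho, eta) {
  if (!is.numeric(eta) || length(eta) != 1L || !(eta > 0))
    stop("'eta' must be a single number > 0", call. = FALSE)
  log_norm <- -(2 * eta - 1) * log(2) - lbeta(eta, eta)
  out <- rep(-Inf, length(rho))
  ok <- is.finite(rho) & abs(rho) < 1
  out[ok] <- (eta - 1) * log1p(-rho[ok]^2) + log_norm
  out
}

#' Log-density of the log-normal distribution
#'
#' Prior used for the likelihood standard deviations sigma1 and sigma2.
#' Returns `-Inf` for `x <= 0`.
#'
#' @param x evaluation point(s).
#' @param mu_log,sigma_log mean and standard deviation of `log(x)`
#'   (`sigma_log > 0`).
#' @return Log-density, vectorized over `x`.
#' @export
lognormal_logpdf <- function(x, mu_log = 0, sigma_log = 1) {
  if (!is.numeric(sigma_log) || !(sigma_log > 0))
    stop("'sigma_log' must be > 0", call. = FALSE)
  out <- rep(-Inf, length(x))
  ok <- is.finite(x) & x > 0
  out[ok] <- stats::dlnorm(x[ok], meanlog = mu_log, sdlog = sigma_log,
                           log = TRUE)
  out
}

#' Log-prior density of a structure-factor amplitude
#'
#' Evaluates the configured amplitude prior at `F`.  Both choices put zero
#' mass on negative amplitudes (`-Inf` log-density); the truncated normal
#' is renormalized by the mass it retains on `[0, Inf)`.
#'
#' @param F amplitude value(s).
#' @param config a [prior_config()].
#' @return Normalized log-density, vectorized over `F`.
#' @export
amplitude_logprior <- function(F, config) {
  if (!inherits(config, "prior_config"))
    stop("'config' must be a prior_config object", call. = FALSE)
  amp <- config$amplitude
  out <- rep(-Inf, length(F))
  if (amp$type == "uniform") {
    ok <- is.finite(F) & F >= 0 & F <= amp$upper
    out[ok] <- -log(amp$upper)
  } else {
    ok <- is.finite(F) & F >= 0
    log_mass <- stats::pnorm(0, amp$mu, amp$sigma, lower.tail = FALSE,
                             log.p = TRUE)
    out[ok] <- stats::dnorm(F[ok], amp$mu, amp$sigma, log = TRUE) - log_mass
  }
  out
}
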