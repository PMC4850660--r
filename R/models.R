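#' Parameter states for the two Bayesian intensity models
#'
#' `mv_params()` holds one state of the multivariate (bivariate-normal)
#' model: amplitudes `F1`, `F2 >= 0`, likelihood standard deviations
#' `sigma1`, `sigma2 > 0` and the within-pair correlation `rho` in (-1, 1).
#' The implied covariance `Sigma = diag(s1, s2) %*% Omega %*% diag(s1, s2)`
#' with `Omega = [[1, rho], [rho, 1]]` is positive definite exactly when
#' these constraints hold.  `uv_params()` is the same without `rho`.
#'
#' @param F1,F2 structure-factor amplitudes, `>= 0`.
#' @param sigma1,sigma2 standard deviations of the I1 and I2 observations,
#'   `> 0`.
#' @param rho within-pair correlation, in (-1, 1) (multivariate only).
#' @return A named list of class `"mv_params"` or `"uv_params"`.
#' @export
mv_params <- function(F1, F2, sigma1, sigma2, rho) {
  p <- list(F1 = F1, F2 = F2, sigma1 = sigma1, sigma2 = sigma2, rho = rho)
  bad <- validate_params(p, c("F1", "F2", "sigma1", "sigma2", "rho"))
  if (!is.null(bad)) stop(bad, call. = FALSE)
  structure(p, class = "mv_params")
}

#' @rdname mv_params
#' @export
uv_params <- function(F1, F2, sigma1, sigma2) {
  p <- list(F1 = F1, F2 = F2, sigma1 = sigma1, sigma2 = sigma2)
  bad <- validate_params(p, c("F1", "F2", "sigma1", "sigma2"))
  if (!is.null(bad)) stop(bad, call. = FALSE)
  structure(p, class = "uv_params")
}

validate_params <- function(p, fields) {
  for (f in fields) {
    x <- p[[f]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      return(paste0("'", f, "' must be a single finite number"))
  }
  if (p$F1 < 0 || p$F2 < 0) return("amplitudes F1, F2 must be >= 0")
  if (p$sigma1 <= 0 || p$sigma2 <= 0) return("sigma1, sigma2 must be > 0")
  if (!is.null(p$rho) && abs(p$rho) >= 1) return("'rho' must lie in (-1, 1)")
  NULL
}

# TRUE when a plain list of values lies inside the model support; used by the
# sampler so out-of-support proposals are rejected without evaluation.
params_in_support <- function(p, multivariate) {
  ok <- is.finite(p$F1) && is.finite(p$F2) && p$F1 >= 0 && p$F2 >= 0 &&
    is.finite(p$sigma1) && is.finite(p$sigma2) &&
    p$sigma1 > 0 && p$sigma2 > 0
  if (multivariate)
    ok <- ok && is.finite(p$rho) && abs(p$rho) < 1
  ok
}

#' Log-likelihood of the multivariate (bivariate-normal) model
#'
#' Each referenced pair `(I1_i, I2_i)` is one draw from a bivariate normal
#' with mean `(F1^2, F2^2)` — intensities are squared amplitudes — and
#' covariance built from `(sigma1, sigma2, rho)`.  The correlation `rho`
#' absorbs the systematic error shared within a pair; it is what lets one
#' strongly negative observation inform its partner's amplitude.
#'
#' The density is evaluated with the closed-form 2x2 expression
#' (`log det Sigma = 2 log sigma1 + 2 log sigma2 + log(1 - rho^2)`), which
#' is faster and better behaved near `|rho| -> 1` than generic matrix
#' routines.
#'
#' @param params an [mv_params()] state (a plain named list with the same
#'   fields is accepted).
#' @param data an [intensity_pairs()] set.
#' @return The summed log-likelihood (a single number).
#' @export
mv_loglik <- function(params, data) {
  data <- as_intensity_pairs(data)
  s1 <- params$sigma1; s2 <- params$sigma2; rho <- params$rho
  if (!params_in_support(params, multivariate = TRUE))
    stop("invalid multivariate parameters", call. = FALSE)
  z1 <- (data$I1 - params$F1^2) / s1
  z2 <- (data$I2 - params$F2^2) / s2
  omr2 <- (1 - rho) * (1 + rho)
  q <- (z1^2 - 2 * rho * z1 * z2 + z2^2) / omr2
  n <- data$n
  -n * log(2 * pi) - n * (log(s1) + log(s2)) - n / 2 * log(omr2) -
    sum(q) / 2
}

#' Log-likelihood of the univariate baseline model
#'
#' The pairing of the data is ignored: the `I1` observations are modelled
#' as i.i.d. `Normal(F1^2, sigma1)` and the `I2` observations as i.i.d.
#' `Normal(F2^2, sigma2)`.  The result is invariant to any permutation
#' applied to `I2` alone.
#'
#' @inheritParams mv_loglik
#' @return The summed log-likelihood (a single number).
#' @export
uv_loglik <- function(params, data) {
  data <- as_intensity_pairs(data)
  if (!params_in_support(params, multivariate = FALSE))
    stop("invalid univariate parameters", call. = FALSE)
  sum(stats::dnorm(data$I1, params$F1^2, params$sigma1, log = TRUE)) +
    sum(stats::dnorm(data$I2, params$F2^2, params$sigma2, log = TRUE))
}

as_intensity_pairs <- function(data) {
  if (inherits(data, "intensity_pairs")) return(data)
  if (is.list(data) && !is.null(data$I1) && !is.null(data$I2))
    return(intensity_pairs(data$I1, data$I2))
  stop("'data' must be an intensity_pairs object", call. = FALSE)
}

#' Unnormalized log-posterior of either model
#'
#' Sum of the model log-likelihood and the log-priors: the amplitude prior
#' on `F1` and `F2`, the log-normal prior on `sigma1` and `sigma2`, and —
#' for the multivariate model — the LKJ prior on `rho`.  Returns `-Inf`
#' whenever any component is out of its support (negative amplitude,
#' non-positive sigma, `|rho| >= 1`); it never returns `NaN`.
#'
#' @param params a named list of parameter values (fields `F1`, `F2`,
#'   `sigma1`, `sigma2` and, for the multivariate model, `rho`).
#' @param data an [intensity_pairs()] set.
#' @param prior_config a [prior_config()].
#' @param model_kind `"multivariate"` or `"univariate"`.
#' @return The unnormalized log-posterior (a single number, possibly
#'   `-Inf`).
#' @export
log_posterior <- function(params, data, prior_config,
                          model_kind = c("multivariate", "univariate")) {
  model_kind <- match.arg(model_kind)
  multivariate <- model_kind == "multivariate"
  if (!params_in_support(params, multivariate)) return(-Inf)
  lp <- amplitude_logprior(params$F1, prior_config) +
    amplitude_logprior(params$F2, prior_config) +
    lognormal_logpdf(params$sigma1, prior_config$sigma_mu_log,
                     prior_config$sigma_sigma_log) +
    lognormal_logpdf(params$sigma2, prior_config$sigma_mu_log,
                     prior_config$sigma_sigma_log)
  if (multivariate)
    lp <- lp + lkj_logpdf_2x2(params$rho, prior_config$lkj_eta)
  if (!is.finite(lp)) return(-Inf)
  ll <- if (multivariate) mv_loglik(params, data) else uv_loglik(params, data)
  out <- lp + ll
  if (is.nan(out)) -Inf else out
}

#' Difference structure-factor amplitude
#'
#' `dF = F1 - F2`, the quantity difference maps and anomalous phasing are
#' built from.  May be negative.  Applied to vectors it acts elementwise,
#' which is how the dF posterior is induced from a trace: transform each
#' posterior sample, never the summaries (the median of per-sample
#' differences is generally not the difference of medians).
#'
#' @param F1,F2 amplitude value(s), `>= 0`.
#' @return `F1 - F2`, vectorized.
#' @export
delta_f <- function(F1, F2) {
  if (any(F1 < 0, na.rm = TRUE) || any(F2 < 0, na.rm = TRUE))
    stop("amplitudes must be >= 0", call. = FALSE)
  F1 - F2
}
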