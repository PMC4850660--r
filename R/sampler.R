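#' MCMC chain configuration
#'
#' Settings for the random-walk Metropolis sampler.  Defaults follow the
#' reference protocol: 50 000 iterations per chain with the first 20 000
#' discarded as burn-in, and two chains whose post-burn-in draws are
#' pooled.
#'
#' @param n_iter total iterations per chain.
#' @param burn_in iterations discarded from the start of each chain
#'   (`burn_in < n_iter`).
#' @param seed master integer seed; each chain derives its own stream from
#'   it.
#' @param proposal_scales named numeric vector of per-parameter proposal
#'   standard deviations, or a single number used for all parameters.
#'   These are starting values when `adapt = TRUE`.
#' @param adapt tune proposal scales during burn-in only (targeting
#'   roughly 20--45% acceptance); scales are frozen afterwards so the
#'   post-burn-in chain is a valid Metropolis chain.
#' @param n_chains number of independent chains (`>= 1`).
#' @return An object of class `"chain_config"`.
#' @export
chain_config <- function(n_iter = 50000L, burn_in = 20000L, seed = 1L,
                         proposal_scales = 0.1, adapt = TRUE,
                         n_chains = 2L) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  n_chains <- as.integer(n_chains)
  if (is.na(n_iter) || n_iter < 2L) stop("'n_iter' must be >= 2", call. = FALSE)
  if (is.na(burn_in) || burn_in < 0L || burn_in >= n_iter)
    stop("'burn_in' must satisfy 0 <= burn_in < n_iter", call. = FALSE)
  if (is.na(n_chains) || n_chains < 1L)
    stop("'n_chains' must be >= 1", call. = FALSE)
  if (!is.numeric(proposal_scales) || any(proposal_scales <= 0))
    stop("'proposal_scales' must be positive", call. = FALSE)
  structure(list(n_iter = n_iter, burn_in = burn_in,
                 seed = as.integer(seed),
                 proposal_scales = proposal_scales,
                 adapt = isTRUE(adapt), n_chains = n_chains),
            class = "chain_config")
}

#' Random-walk Metropolis sampler
#'
#' Samples from an unnormalized log target by Metropolis-within-Gibbs:
#' each iteration sweeps the parameters in order, proposing a Gaussian
#' perturbation of one coordinate at a time and accepting with probability
#' `min(1, exp(delta log target))`.  Proposals falling where the target is
#' `-Inf` are rejected outright, which is how hard support constraints
#' (e.g. nonnegative amplitudes) are enforced.
#'
#' During burn-in (only), proposal scales are adapted every 200 iterations
#' toward a 20--45% acceptance window; after burn-in the scales are frozen.
#' Runs `config$n_chains` chains from per-chain seeds derived
#' deterministically from the master seed; identical inputs and seed give
#' bitwise-identical output.
#'
#' @param logpost function taking a named numeric vector and returning the
#'   unnormalized log target (may be `-Inf`, never `NaN`).
#' @param init named numeric vector; `logpost(init)` must be finite.
#' @param config a [chain_config()].
#' @return An object of class `"metropolis_trace"`: list with `samples`
#'   (pooled post-burn-in draws, one column per parameter), `chain`
#'   (chain index of each row), `acceptance_rate` (per parameter,
#'   post-burn-in, averaged over chains), `proposal_scales` (final, per
#'   chain), `config` and `seed`.
#' @export
run_metropolis <- function(logpost, init, config = chain_config()) {
  if (!inherits(config, "chain_config"))
    stop("'config' must be a chain_config object", call. = FALSE)
  if (is.null(names(init)) || any(!nzchar(names(init))))
    stop("'init' must be a fully named numeric vector", call. = FALSE)
  p <- length(init)
  lp0 <- logpost(init)
  if (!is.finite(lp0))
    stop("log target is not finite at 'init'; re-initialize the chain",
         call. = FALSE)
  scales0 <- config$proposal_scales
  if (length(scales0) == 1L) scales0 <- rep(scales0, p)
  if (length(scales0) != p)
    stop("'proposal_scales' must have length 1 or length(init)",
         call. = FALSE)
  scales0 <- as.numeric(scales0)

  n_keep <- config$n_iter - config$burn_in
  chains <- vector("list", config$n_chains)
  acc_mat <- matrix(0, config$n_chains, p)
  final_scales <- matrix(0, config$n_chains, p,
                         dimnames = list(NULL, names(init)))

  for (ch in seq_len(config$n_chains)) {
    res <- with_rng_seed(derive_seed(config$seed, ch), {
      metropolis_chain(logpost, init, config$n_iter, config$burn_in,
                       scales0, config$adapt)
    })
    colnames(res$samples) <- names(init)
    chains[[ch]] <- res$samples
    acc_mat[ch, ] <- res$acceptance
    final_scales[ch, ] <- res$scales
  }

  acceptance <- colMeans(acc_mat)
  names(acceptance) <- names(init)
  if (any(acceptance < 0.01))
    warning("post-burn-in acceptance rate below 1% for parameter(s): ",
            paste(names(init)[acceptance < 0.01], collapse = ", "),
            call. = FALSE)
  structure(list(samples = do.call(rbind, chains),
                 chain = rep(seq_len(config$n_chains), each = n_keep),
                 acceptance_rate = acceptance,
                 proposal_scales = final_scales,
                 config = config, seed = config$seed),
            class = "metropolis_trace")
}

# One chain; RNG state is assumed already seeded by the caller.
metropolis_chain <- function(logpost, init, n_iter, burn_in, scales, adapt) {
  p <- length(init)
  x <- as.numeric(init)
  names(x) <- names(init)
  lp <- logpost(x)
  n_keep <- n_iter - burn_in
  out <- matrix(NA_real_, n_keep, p)
  acc_keep <- integer(p)     # accepted moves after burn-in
  acc_win <- integer(p)      # accepted moves in current adaptation window
  win <- 200L
  n_win <- 0L
  for (it in seq_len(n_iter)) {
    # pre-draw this iteration's innovations and uniforms in fixed order
    eps <- stats::rnorm(p)
    us <- stats::runif(p)
    for (j in seq_len(p)) {
      prop <- x
      prop[j] <- x[j] + scales[j] * eps[j]
      lp_prop <- logpost(prop)
      if (is.finite(lp_prop) && log(us[j]) < lp_prop - lp) {
        x <- prop
        lp <- lp_prop
        acc_win[j] <- acc_win[j] + 1L
        if (it > burn_in) acc_keep[j] <- acc_keep[j] + 1L
      }
    }
    n_win <- n_win + 1L
    if (adapt && it <= burn_in && n_win == win) {
      rate <- acc_win / win
      scales <- ifelse(rate > 0.45, scales * 1.5,
                       ifelse(rate < 0.20, scales / 1.5, scales))
      scales <- pmin(pmax(scales, 1e-8), 1e8)
      acc_win <- integer(p)
      n_win <- 0L
    } else if (n_win == win) {
      acc_win <- integer(p)
      n_win <- 0L
    }
    if (it > burn_in) out[it - burn_in, ] <- x
  }
  list(samples = out, acceptance = acc_keep / n_keep, scales = scales)
}

#' Normalized autocorrelation function of a chain component
#'
#' @param x numeric vector (one parameter's chain).
#' @param max_lag largest lag to report (`< length(x)`).
#' @return Numeric vector of length `max_lag + 1`; element k + 1 is the
#'   autocorrelation at lag k, with lag 0 exactly 1.
#' @export
autocorrelation <- function(x, max_lag) {
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  if (length(x) <= max_lag)
    stop("'x' must be longer than 'max_lag'", call. = FALSE)
  if (stats::var(x) == 0)
    stop("autocorrelation is undefined for a constant sequence",
         call. = FALSE)
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
  as.numeric(a$acf)
}

#' Effective sample size of a chain component
#'
#' Initial-positive-sequence estimator: the integrated autocorrelation time
#' is accumulated over consecutive lag pairs `(2m, 2m + 1)` until a pair
#' sum turns negative, and `ESS = n / tau`, capped at `n`.
#'
#' @param x numeric vector (one parameter's chain).
#' @return Estimated effective sample size, in `(0, length(x)]`.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 4L) stop("chain too short for an ESS estimate", call. = FALSE)
  if (stats::var(x) == 0) return(1)
  max_lag <- min(n - 1L, 2000L)
  rho <- autocorrelation(x, max_lag)
  # Geyer pairs: (rho_0 + rho_1), (rho_2 + rho_3), ...
  m_max <- (max_lag + 1L) %/% 2L
  tau <- 0
  for (m in seq_len(m_max)) {
    g <- rho[2L * m - 1L] + rho[2L * m]
    if (g <= 0) break
    tau <- tau + g
  }
  tau <- max(2 * tau - 1, 1)
  min(n, n / tau)
}
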