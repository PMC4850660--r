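#' Generative error model for referenced intensity pairs
#'
#' Describes how two intensity observation sets of a single reflection are
#' produced from true structure-factor amplitudes.  Each pair i shares one
#' systematic error draw s_i ~ Normal(mu_sys, sigma_sys) — the component a
#' referencing data-collection strategy (inverse beam, interleaved pump-probe
#' cycles) keeps common to both measurements — while r_1i, r_2i ~
#' Normal(0, sigma_ran) are independent random errors that referencing cannot
#' remove:
#'
#'   I1_i = F1_true^2 + s_i + r_1i,
#'   I2_i = F2_true^2 + s_i + r_2i.
#'
#' Observations may be negative; nothing is clipped.  Handling negative
#' intensities is the point of the downstream Bayesian models.
#'
#' @param F1_true,F2_true true structure-factor amplitudes (dimensionless,
#'   `>= 0`); the true mean intensities are their squares.
#' @param mu_sys mean of the shared systematic error (intensity units).
#' @param sigma_sys standard deviation of the shared systematic error
#'   (`>= 0`).
#' @param sigma_ran standard deviation of the independent random error on
#'   each observation (`>= 0`).
#' @param n_pairs number of referenced pairs to generate (`>= 1`).
#'
#' @return An object of class `"error_model"`: a named list of the six
#'   generative parameters.
#' @seealso [generate_pairs()]
#' @examples
#' em <- error_model(F1_true = 0.1, F2_true = 0.7, mu_sys = -0.5,
#'                   sigma_sys = 1.5, sigma_ran = 0.3, n_pairs = 200)
#' pairs <- generate_pairs(em, seed = 1)
#' mean(pairs$I1 - pairs$I2)  # concentrates near F1^2 - F2^2 = -0.48
#' @export
error_model <- function(F1_true, F2_true, mu_sys, sigma_sys, sigma_ran,
                        n_pairs) {
  check_scalar <- function(x, name, lower = -Inf, integer = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", name, "' must be a single finite number", call. = FALSE)
    if (x < lower)
      stop("'", name, "' must be >= ", lower, " (got ", x, ")", call. = FALSE)
    if (integer && x != round(x))
      stop("'", name, "' must be a whole number (got ", x, ")", call. = FALSE)
    as.numeric(x)
  }
  m <- list(
    F1_true   = check_scalar(F1_true, "F1_true", lower = 0),
    F2_true   = check_scalar(F2_true, "F2_true", lower = 0),
    mu_sys    = check_scalar(mu_sys, "mu_sys"),
    sigma_sys = check_scalar(sigma_sys, "sigma_sys", lower = 0),
    sigma_ran = check_scalar(sigma_ran, "sigma_ran", lower = 0),
    n_pairs   = as.integer(check_scalar(n_pairs, "n_pairs", lower = 1,
                                        integer = TRUE))
  )
  structure(m, class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("Referenced-pair error model\n")
  cat(sprintf("  F1_true = %g, F2_true = %g (true dF = %g)\n",
              x$F1_true, x$F2_true, x$F1_true - x$F2_true))
  cat(sprintf("  systematic error: Normal(mu = %g, sd = %g), shared per pair\n",
              x$mu_sys, x$sigma_sys))
  cat(sprintf("  random error:     Normal(0, sd = %g), independent\n",
              x$sigma_ran))
  cat(sprintf("  n_pairs = %d\n", x$n_pairs))
  invisible(x)
}

#' Paired intensity observations of one reflection
#'
#' Container for aligned intensity observations: element i of `I1` is
#' referenced against element i of `I2` (same pair, shared systematic
#' error).  Values may be negative.
#'
#' @param I1,I2 numeric vectors of equal positive length.
#' @return An object of class `"intensity_pairs"` with fields `I1`, `I2`
#'   and `n`.
#' @export
intensity_pairs <- function(I1, I2) {
  if (!is.numeric(I1) || !is.numeric(I2))
    stop("'I1' and 'I2' must be numeric vectors", call. = FALSE)
  if (length(I1) != length(I2))
    stop("'I1' and 'I2' must have equal length (got ",
         length(I1), " and ", length(I2), ")", call. = FALSE)
  if (length(I1) < 1L)
    stop("at least one intensity pair is required", call. = FALSE)
  if (anyNA(I1) || anyNA(I2) || !all(is.finite(I1)) || !all(is.finite(I2)))
    stop("intensities must be finite and non-missing", call. = FALSE)
  structure(list(I1 = as.numeric(I1), I2 = as.numeric(I2),
                 n = length(I1)),
            class = "intensity_pairs")
}

#' @export
print.intensity_pairs <- function(x, ...) {
  cat(sprintf("Intensity pair set: %d referenced pairs\n", x$n))
  cat(sprintf("  mean(I1) = %.4g, mean(I2) = %.4g, mean(I1 - I2) = %.4g\n",
              mean(x$I1), mean(x$I2), mean(x$I1 - x$I2)))
  cat(sprintf("  cor(I1, I2) = %.3f\n",
              if (x$n > 1) stats::cor(x$I1, x$I2) else NA_real_))
  invisible(x)
}

#' Generate referenced intensity pairs from an error model
#'
#' Draws `n_pairs` observation pairs.  For pair i the draws are taken in the
#' fixed order (s_i, r_1i, r_2i) from a single generator seeded with `seed`,
#' so identical `(model, seed)` arguments give bitwise-identical output on
#' any platform with R's default RNG.
#'
#' @param model an [error_model()].
#' @param seed integer seed for the random number generator.
#' @return An [intensity_pairs()] object of length `model$n_pairs`.
#' @export
generate_pairs <- function(model, seed) {
  if (!inherits(model, "error_model"))
    stop("'model' must be an error_model object", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  n <- model$n_pairs
  draws <- with_rng_seed(as.integer(seed), {
    # one sequential stream, consumed as (s_1, r1_1, r2_1, s_2, ...)
    stats::rnorm(3L * n)
  })
  s  <- model$mu_sys + model$sigma_sys * draws[seq(1L, 3L * n, by = 3L)]
  r1 <- model$sigma_ran * draws[seq(2L, 3L * n, by = 3L)]
  r2 <- model$sigma_ran * draws[seq(3L, 3L * n, by = 3L)]
  intensity_pairs(I1 = model$F1_true^2 + s + r1,
                  I2 = model$F2_true^2 + s + r2)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-unit seed stream: unit `index` under `master` always maps
# to the same child seed, and adding units never perturbs earlier ones.
derive_seed <- function(master, index) {
  m <- as.double(master) %% 2147483647
  # two rounds of a Lehmer-style mix keep children of nearby masters apart
  x <- (m * 48271 + as.double(index)) %% 2147483647
  x <- (x * 69621 + 1) %% 2147483647
  as.integer(x)
}
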