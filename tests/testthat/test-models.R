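# Likelihoods and log-posteriors of the two amplitude models.

test_that("single zero-residual pair gives the density normalizers only", {
  d <- intensity_pairs(4, 1)
  mv <- mv_params(F1 = 2, F2 = 1, sigma1 = 1, sigma2 = 1, rho = 0)
  uv <- uv_params(F1 = 2, F2 = 1, sigma1 = 1, sigma2 = 1)
  expect_equal(mv_loglik(mv, d), 2 * log(1 / sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_equal(uv_loglik(uv, d), 2 * log(1 / sqrt(2 * pi)),
               tolerance = 1e-12)
})

test_that("bivariate likelihood factorizes at rho = 0", {
  set.seed(11)
  for (i in 1:10) {
    p <- random_mv_params()
    p$rho <- 0
    d <- random_pairs(25)
    expect_equal(mv_loglik(p, d),
                 uv_loglik(uv_params(p$F1, p$F2, p$sigma1, p$sigma2), d),
                 tolerance = 1e-10)
  }
})

test_that("closed-form 2x2 likelihood matches the dense-matrix oracle", {
  set.seed(12)
  for (i in 1:100) {
    p <- random_mv_params()
    d <- random_pairs(15)
    expect_equal(mv_loglik(p, d), mv_loglik_dense(p, d),
                 tolerance = 1e-10)
  }
})

test_that("univariate likelihood ignores the pairing", {
  set.seed(13)
  d <- random_pairs(30)
  p <- uv_params(1, 0.5, 1.2, 0.8)
  shuffled <- intensity_pairs(d$I1, sample(d$I2))
  expect_equal(uv_loglik(p, d), uv_loglik(p, shuffled), tolerance = 1e-12)
})

test_that("log-posterior is -Inf outside the support and never NaN", {
  d <- random_pairs(10)
  pc <- prior_config()
  base <- list(F1 = 1, F2 = 0.5, sigma1 = 1, sigma2 = 1, rho = 0.3)
  expect_identical(log_posterior(modifyList(base, list(F1 = -0.1)),
                                 d, pc, "multivariate"), -Inf)
  expect_identical(log_posterior(modifyList(base, list(sigma1 = 0)),
                                 d, pc, "multivariate"), -Inf)
  expect_identical(log_posterior(modifyList(base, list(rho = 1)),
                                 d, pc, "multivariate"), -Inf)
  # no prior singularity at |rho| -> 1 when eta = 1
  near <- log_posterior(modifyList(base, list(rho = 1 - 1e-9)),
                        d, pc, "multivariate")
  expect_true(is.finite(near))
  # random probes, including wild values, never produce NaN
  set.seed(14)
  for (i in 1:50) {
    p <- list(F1 = rnorm(1, 0, 5), F2 = rnorm(1, 0, 5),
              sigma1 = rnorm(1, 0, 3), sigma2 = rnorm(1, 0, 3),
              rho = rnorm(1, 0, 1))
    expect_false(is.nan(log_posterior(p, d, pc, "multivariate")))
  }
})

test_that("log-posterior differences decompose into component differences", {
  set.seed(15)
  d <- random_pairs(20)
  pc <- prior_config(amplitude = list(type = "truncated_normal",
                                      mu = 0.7, sigma = 7),
                     sigma_mu_log = 0.2, sigma_sigma_log = 0.8,
                     lkj_eta = 2)
  for (i in 1:10) {
    a <- random_mv_params()
    b <- random_mv_params()
    comp <- function(p) {
      mv_loglik(p, d) +
        amplitude_logprior(p$F1, pc) + amplitude_logprior(p$F2, pc) +
        lognormal_logpdf(p$sigma1, 0.2, 0.8) +
        lognormal_logpdf(p$sigma2, 0.2, 0.8) +
        lkj_logpdf_2x2(p$rho, 2)
    }
    expect_equal(log_posterior(a, d, pc, "multivariate") -
                   log_posterior(b, d, pc, "multivariate"),
                 comp(a) - comp(b), tolerance = 1e-10)
  }
})

test_that("sampling-scale log-posterior equals the natural one plus Jacobian", {
  set.seed(16)
  d <- random_pairs(20)
  for (kind in c("multivariate", "univariate")) {
    pc <- prior_config()
    f <- refdelta:::unconstrained_logpost(d, pc, kind)
    for (i in 1:10) {
      p <- random_mv_params()
      theta <- c(F1 = p$F1, F2 = p$F2,
                 log_sigma1 = log(p$sigma1), log_sigma2 = log(p$sigma2))
      jac <- log(p$sigma1) + log(p$sigma2)
      if (kind == "multivariate") {
        theta <- c(theta, atanh_rho = atanh(p$rho))
        jac <- jac + log(1 - p$rho^2)
      }
      expect_equal(f(theta),
                   log_posterior(p, d, pc, kind) + jac,
                   tolerance = 1e-8)
    }
  }
})

test_that("difference amplitude is a per-sample transform", {
  expect_identical(delta_f(0.7, 0.7), 0)
  expect_error(delta_f(-0.1, 0.2), ">= 0")
  # a skewed joint trace where median of differences != difference of medians
  F1 <- c(1, 2, 3, 4, 100)
  F2 <- c(0, 0, 50, 50, 50)
  dF <- delta_f(F1, F2)
  expect_equal(median(dF), 1)
  expect_equal(median(F1) - median(F2), -47)
  expect_false(isTRUE(all.equal(median(dF), median(F1) - median(F2))))
})
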