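# HDI, posterior summaries, PPC ellipses and the comparison table.

test_that("HDI of a uniform grid takes the lowest tied window", {
  expect_equal(hdi(1:100), c(low = 1, high = 95))
  expect_equal(hdi(sample(1:100)), c(low = 1, high = 95))
})

test_that("HDI matches the brute-force window scan exactly", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(20:1000, 1)
    x <- switch(1 + i %% 3,
                rnorm(n), rexp(n), rt(n, df = 3))
    mass <- sample(c(0.5, 0.8, 0.95), 1)
    expect_identical(unname(hdi(x, mass)), hdi_bruteforce(x, mass))
  }
})

test_that("HDI approaches closed-form intervals for known shapes", {
  set.seed(32)
  z <- rnorm(5e5)
  h <- hdi(z)
  expect_lt(abs(h[["low"]] + 1.96), 0.03)
  expect_lt(abs(h[["high"]] - 1.96), 0.03)
  e <- rexp(1e5)
  he <- hdi(e)
  expect_lt(he[["low"]], 0.02)             # hugs the mode at 0
  expect_lt(abs(he[["high"]] + log(0.05)), 0.1)
  # symmetric unimodal: HDI agrees with the equal-tailed interval
  q <- quantile(z, c(0.025, 0.975))
  expect_lt(abs(h[["low"]] - q[[1]]), 0.03)
  expect_lt(abs(h[["high"]] - q[[2]]), 0.03)
})

test_that("HDI contains at least the requested sample mass", {
  set.seed(33)
  x <- rlnorm(5000)
  h <- hdi(x, 0.95)
  inside <- mean(x >= h[["low"]] & x <= h[["high"]])
  expect_gte(inside, 0.95 - 1 / length(x))
  expect_lt(h[["low"]], h[["high"]])
})

test_that("HDI rejects degenerate requests", {
  expect_error(hdi(rnorm(10)), "at least 20")
  expect_error(hdi(rnorm(100), mass = 1), "mass")
})

test_that("posterior summaries derive dF per sample", {
  em <- error_model(0.1, 0.7, -0.5, 1.5, 0.3, 100)
  d <- generate_pairs(em, seed = 6)
  fit <- fit_pairs(d, "multivariate", chain = quick_chain(seed = 6))
  s <- summarize_posterior(fit)
  expect_setequal(s$variable, c("F1", "F2", "sigma1", "sigma2", "rho", "dF"))
  # sort-oracle median of the per-sample differences
  dF <- sort(fit$samples$F1 - fit$samples$F2)
  expect_equal(s$median[s$variable == "dF"], median(dF), tolerance = 1e-12)
  expect_equal(s$width, s$hdi_high - s$hdi_low, tolerance = 1e-12)
})

test_that("summaries of a constant trace have zero width", {
  fit <- structure(list(samples = data.frame(F1 = rep(2, 100))),
                   class = "ref_fit")
  s <- summarize_posterior(fit)
  expect_equal(s$median, 2)
  expect_equal(s$width, 0)
})

test_that("PPC ellipse geometry: isotropic and near-degenerate cases", {
  mk_fit <- function(s1, s2, rho) {
    structure(list(samples = data.frame(F1 = 1, F2 = 0.5, sigma1 = s1,
                                        sigma2 = s2, rho = rho,
                                        dF = 0.5),
                   model_kind = "multivariate"),
              class = "ref_fit")
  }
  r <- sqrt(qchisq(0.95, 2))
  iso <- ppc_ellipses(mk_fit(1.3, 1.3, 0), n_draws = 1)
  expect_equal(iso$len1, r * 1.3, tolerance = 1e-10)
  expect_equal(iso$len2, r * 1.3, tolerance = 1e-10)
  expect_equal(c(iso$centre1, iso$centre2), c(1, 0.25))
  deg <- ppc_ellipses(mk_fit(1, 1, 0.9999), n_draws = 1)
  expect_lt(deg$len2, 0.02 * deg$len1)
  expect_equal(abs(c(deg$dir1_x, deg$dir1_y)), rep(1 / sqrt(2), 2),
               tolerance = 1e-3)
})

test_that("95% ellipse of a bivariate normal covers 95% of its own draws", {
  s1 <- 1.2; s2 <- 0.7; rho <- 0.6
  fit <- structure(list(samples = data.frame(F1 = 0, F2 = 0, sigma1 = s1,
                                             sigma2 = s2, rho = rho,
                                             dF = 0),
                        model_kind = "multivariate"),
                   class = "ref_fit")
  e <- ppc_ellipses(fit, n_draws = 1)
  set.seed(34)
  n <- 1e5
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- s1 * z1
  y <- s2 * (rho * z1 + sqrt(1 - rho^2) * z2)
  # project onto the ellipse axes and test the normalized radius
  u <- cbind(x - e$centre1, y - e$centre2)
  a1 <- c(e$dir1_x, e$dir1_y); a2 <- c(e$dir2_x, e$dir2_y)
  rad <- (u %*% a1 / e$len1)^2 + (u %*% a2 / e$len2)^2
  expect_lt(abs(mean(rad <= 1) - 0.95), 0.01)
})

test_that("comparison table recovers truth in the noiseless limit", {
  grid <- data.frame(F1_true = 1.5, F2_true = 0.5, mu_sys = 0,
                     sigma_sys = 0.02, sigma_ran = 0.02, n_pairs = 50)
  tab <- comparison_table(grid, chain = quick_chain(), seed = 11)
  expect_lt(abs(tab$F1_mv - 1.5), 0.05)
  expect_lt(abs(tab$F1_uv - 1.5), 0.05)
  expect_lt(abs(tab$dF_mv - 1.0), 0.05)
  expect_lt(abs(tab$dF_uv - 1.0), 0.05)
  # pure function of (grid, seeds)
  tab2 <- comparison_table(grid, chain = quick_chain(), seed = 11)
  expect_identical(tab, tab2)
})
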