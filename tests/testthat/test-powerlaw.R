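test_that("outlier trimming removes isolated extremes only", {
  # log-dense sample: every gap far below 3% of the range
  dense <- 10^seq(0, 2, by = 0.01)
  expect_equal(remove_size_outliers(dense), dense)

  s <- c(seq(1, 10, by = 0.1), 1e6)
  expect_equal(remove_size_outliers(s), seq(1, 10, by = 0.1))

  # a big gap deep in the interior deletes nothing
  interior <- c(10^seq(0, 1, by = 0.01), 10^seq(3, 4, by = 0.01))
  expect_equal(remove_size_outliers(interior), interior)

  # uniform log-gap exactly at the threshold: strict inequality keeps all
  geo <- c(1, 10, 100)  # gaps 1.0 decade, range 2, thr = 0.5 * 2 = 1.0
  expect_equal(remove_size_outliers(geo, gap_frac = 0.5), geo)
  # ... and a suprathreshold extreme gap peels the extreme sample
  expect_equal(remove_size_outliers(c(1, 1.1, 1.2, 100), gap_frac = 0.4),
               c(1, 1.1, 1.2))

  expect_equal(remove_size_outliers(c(1, 100)), c(1, 100))
  expect_error(remove_size_outliers(c(-1, 2, 3)), "positive")
})

test_that("truncated density integrates to 1 for every grid exponent", {
  for (tau in seq(0.7, 2, by = 0.02)) {
    I <- integrate(crackling:::dtruncpl, 0.5, 500, tau = tau,
                   s_min = 0.5, s_max = 500, rel.tol = 1e-9)$value
    expect_equal(I, 1, tolerance = 1e-6)
  }
})

test_that("grid MLE equals brute-force likelihood with numeric normalization", {
  set.seed(20)
  grid <- seq(0.7, 2, by = 0.02)
  for (i in 1:10) {
    tau_true <- runif(1, 0.8, 1.9)
    s <- sample_truncated_powerlaw(300, tau_true, 1, 1e3)
    fit <- fit_truncated_mle(s, 1, 1e3, grid)
    ll_ref <- vapply(grid, function(tg) numint_loglik(s, tg, 1, 1e3),
                     numeric(1))
    expect_equal(fit$tau, grid[which.max(ll_ref)])
    expect_equal(fit$logL, max(ll_ref), tolerance = 1e-8)
  }
})

test_that("the MLE recovers known exponents including the tau = 1 branch", {
  s <- sample_truncated_powerlaw(1e4, 1.5, 1, 1e4, seed = 21)
  expect_lt(abs(fit_truncated_mle(s, 1, 1e4)$tau - 1.5), 0.04)

  s1 <- sample_truncated_powerlaw(2e4, 1.0, 1, 1e4, seed = 22)
  expect_lt(abs(fit_truncated_mle(s1, 1, 1e4)$tau - 1.0), 0.021)

  expect_error(fit_truncated_mle(s, 10, 1), "s_min")
  expect_error(fit_truncated_mle(s[1:5], 1, 1e4), "insufficient tail")
})

test_that("goodness-of-fit separates self-consistent draws from misfits", {
  set.seed(23)
  Fs <- replicate(10, {
    s <- sample_truncated_powerlaw(1000, 1.5, 1, 1e3)
    goodness_of_fit(s, tau = 1.5, s_min = 1, s_max = 1e3, n_surrogate = 100)
  })
  expect_gte(mean(Fs >= 0.9), 0.8)

  # exponential sizes forced onto 3 decades are a visible misfit
  set.seed(24)
  e <- rexp(1000, rate = 1) + 1
  e <- e[e <= 1000]
  Fm <- goodness_of_fit(e, tau = 1.5, s_min = 1, s_max = 1000,
                        n_surrogate = 100)
  expect_lt(Fm, 0.75)

  expect_error(goodness_of_fit(e, tau = 1.5, s_min = 1, s_max = 1e3,
                               n_surrogate = 0), "n_surrogate")
})

test_that("range fitting is scale invariant and monotone in the criterion", {
  s <- sample_truncated_powerlaw(2000, 1.4, 1, 1e3, seed = 25)
  f1 <- fit_power_law_range(s, n_surrogate = 100, seed = 26)
  f2 <- fit_power_law_range(s * 1000, n_surrogate = 100, seed = 26)
  expect_equal(f1$range_decades, f2$range_decades)
  expect_equal(f1$tau, f2$tau)
  expect_equal(f2$s_min, f1$s_min * 1000, tolerance = 1e-9)

  f_hi <- fit_power_law_range(s, F_criterion = 0.95, n_surrogate = 100,
                              seed = 26)
  expect_lte(f_hi$range_decades, f1$range_decades)

  expect_equal(fit_power_law_range(rep(2, 100))$range_decades, 0)
})

test_that("exponent uncertainty shrinks with sample size", {
  fits <- lapply(c(100, 1000, 10000), function(n) {
    s <- sample_truncated_powerlaw(n, 1.5, 1, 1e3, seed = 30 + n)
    f <- fit_power_law_range(s, n_surrogate = 100, seed = 31)
    exponent_uncertainty(s, f, n_surrogate = 200, seed = 32)
  })
  tv <- vapply(fits, `[[`, numeric(1), "tau_var")
  expect_true(all(tv >= 0))
  expect_gt(tv[1], tv[3])
  expect_lt(tv[2], 0.5)

  bad <- fit_power_law_range(rep(2, 100))
  expect_error(exponent_uncertainty(rep(2, 100), bad), "positive range")
})

test_that("band slopes of a symmetric envelope cancel", {
  centers <- 10^seq(0, 3, by = 0.1)
  lower <- 0.5 * centers^-1.5
  upper <- 2.0 * centers^-1.5
  sl <- crackling:::band_slopes(centers, lower, upper)
  expect_equal(sl[["tau_up"]], 1.5, tolerance = 1e-9)
  expect_equal(abs(sl[["tau_up"]] - sl[["tau_lo"]]) / 2, 0, tolerance = 1e-9)
})
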