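test_that("inverse-CDF sampling matches the analytic distribution", {
  # tau = 1: log10(s) is uniform
  s <- sample_truncated_powerlaw(1e4, 1, 1, 10, seed = 100)
  ks <- suppressWarnings(ks.test(log10(s), "punif", 0, 1))
  expect_lt(unname(ks$statistic), 0.02)

  # CDF endpoints
  expect_equal(crackling:::qtruncpl(0, 1.5, 2, 100), 2)
  expect_equal(crackling:::qtruncpl(1, 1.5, 2, 100), 100)

  # Dvoretzky-Kiefer-Wolfowitz band around the analytic CDF at 99%
  s2 <- sample_truncated_powerlaw(1e4, 1.5, 1, 1e4, seed = 101)
  grid <- 10^seq(0, 4, length.out = 200)
  emp <- ecdf(s2)(grid)
  ana <- crackling:::ptruncpl(grid, 1.5, 1, 1e4)
  expect_lt(max(abs(emp - ana)), sqrt(log(2 / 0.01) / (2 * 1e4)))

  expect_error(sample_truncated_powerlaw(10, 1.5, 5, 2), "s_min")
  expect_error(sample_truncated_powerlaw(0, 1.5, 1, 10), "n")
})

test_that("sample means match numerical quadrature within 3 standard errors", {
  for (tau in c(0.8, 1.0, 1.5, 2.0)) {
    s <- sample_truncated_powerlaw(1e4, tau, 1, 1e3, seed = 102 + tau * 10)
    m_ana <- integrate(function(x) x * crackling:::dtruncpl(x, tau, 1, 1e3),
                       1, 1e3, rel.tol = 1e-10)$value
    expect_lt(abs(mean(s) - m_ana), 3 * sd(s) / sqrt(length(s)))
  }
})

test_that("planted event series round-trip through event extraction", {
  one <- make_event_series(1.0, dt = 1, seed = 103)
  ev <- extract_events(one)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$size - 1.0) / 1.0, 0.02)

  flat <- make_event_series(numeric(0))
  expect_equal(nrow(extract_events(flat)), 0)

  sizes <- sample_truncated_powerlaw(1000, 1.5, 0.01, 100, seed = 104)
  ser <- make_event_series(sizes, dt = 1, seed = 105)
  expect_equal(median(ser$values), 0)
  ev2 <- extract_events(ser)
  expect_equal(nrow(ev2), 1000)
  expect_equal(sort(ev2$size), sort(sizes), tolerance = 1e-9)
  fit <- fit_power_law_range(ev2$size, n_surrogate = 200, seed = 106)
  expect_lt(abs(fit$tau - 1.5), 0.1)
  expect_lt(abs(fit$range_decades - 4), 0.4)

  expect_error(make_event_series(c(1, -2)), "positive")
  expect_error(make_event_series(1, gap_factor = 0.5), "gap_factor")
})

test_that("the planted population has the anticorrelated canceling structure", {
  pp <- planted_fixture()
  expect_equal(dim(pp$activity), c(300, 10000))
  expect_lte(cor(pp$latent$A$values, pp$latent$B$values), -0.5)

  gm_A <- colMeans(pp$activity[pp$membership == "groupA", ])
  gm_B <- colMeans(pp$activity[pp$membership == "groupB", ])
  expect_lt(cor(gm_A, gm_B), -0.5)
  pop <- colMeans(pp$activity[pp$membership != "noise", ])
  expect_lt(var(pop), 0.1 * var(gm_A))

  # behavior shares event times with the driver
  expect_gt(cor(pp$behaviors$behavior$values, pp$latent$A$values), 0.6)

  # bit-reproducible
  pp2 <- make_planted_population(n_neurons = 300,
                                 group_sizes = c(groupA = 60, groupB = 60),
                                 t_samples = 10000, dt = 1 / 3, seed = 77)
  expect_identical(pp$activity, pp2$activity)
})

test_that("vanishing noise drives within-group correlations to 1", {
  pp <- make_planted_population(n_neurons = 30,
                                group_sizes = c(groupA = 10, groupB = 10),
                                t_samples = 3000, dt = 1, noise_sd = 1e-6,
                                seed = 107)
  a <- pp$activity[1:10, ]
  cors <- cor(t(a))
  expect_gt(min(cors), 0.999)
})
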