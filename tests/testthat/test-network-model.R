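small_config <- function(...) {
  network_config(group_sizes = c("e+" = 80, "e-" = 80, "i+" = 20, "i-" = 20),
                 ...)
}

test_that("connectivity is eigenvalue-normalized with signed blocks", {
  cfg <- small_config()
  W <- build_connectivity(cfg, seed = 80)
  ev <- eigen(as.matrix(W), only.values = TRUE)$values
  expect_lt(abs(max(Mod(ev)) - 1), 1e-9)
  expect_true(all(diag(as.matrix(W)) == 0))
  # one shared weight magnitude, sign by source population
  Wd <- as.matrix(W)
  mags <- unique(round(abs(Wd[Wd != 0]), 12))
  expect_length(mags, 1)
  expect_true(all(Wd[, 161:200][Wd[, 161:200] != 0] < 0))  # inhibitory sources
  expect_true(all(Wd[, 1:80][Wd[, 1:80] != 0] > 0))        # e+ sources

  # Lambda scales every entry linearly for the same wiring seed
  cfg2 <- small_config(Lambda = 2)
  W2 <- build_connectivity(cfg2, seed = 80)
  expect_equal(as.matrix(W2), 2 * as.matrix(W), tolerance = 1e-12)

  # realized block density matches the Bernoulli mask probability
  dense_block <- as.matrix(W)[1:80, 1:80]
  expect_equal(mean(dense_block[row(dense_block) != col(dense_block)] != 0),
               0.5, tolerance = 0.02)

  empty <- small_config(density = matrix(0, 4, 4))
  expect_error(build_connectivity(empty), "spectral radius")
})

test_that("simulation honors quiescence, saturation and Bernoulli rates", {
  Wz <- Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(8, 8))
  grp <- rep(1:4, each = 2)
  run0 <- simulate_network(Wz, eta = 0, steps = 200, burn_in = 0, groups = grp)
  expect_true(all(run0$population_mean == 0))

  run1 <- simulate_network(Wz, eta = 1, steps = 200, burn_in = 0, groups = grp)
  expect_true(all(run1$population_mean == 1))

  W1 <- Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(1, 1))
  run <- simulate_network(W1, eta = 0.3, steps = 1e5, burn_in = 0,
                          groups = 1, seed = 81)
  expect_lt(abs(mean(run$group_means[1, ]) - 0.3), 0.005)

  expect_error(simulate_network(Wz, eta = -0.1, steps = 10, groups = grp),
               "non-negative")
})

test_that("runs are bit-reproducible under a fixed seed", {
  cfg <- small_config()
  r1 <- run_model(cfg, steps = 2000, burn_in = 200, seed = 82)
  r2 <- run_model(cfg, steps = 2000, burn_in = 200, seed = 82)
  expect_identical(r1$group_means, r2$group_means)
  r3 <- run_model(cfg, steps = 2000, burn_in = 200, seed = 83)
  expect_false(identical(r1$group_means, r3$group_means))
})

test_that("the raster is returned on request and matches the group means", {
  cfg <- small_config()
  run <- run_model(cfg, steps = 300, burn_in = 100, keep_states = TRUE,
                   seed = 84)
  expect_equal(dim(run$states), c(200, 300))
  expect_true(all(run$states %in% 0:1))
  expect_equal(colMeans(run$states[1:80, ]),
               unname(run$group_means["e+", ]))
})

test_that("analyze_run reports correlations, fits and switching", {
  cfg <- small_config()
  run <- run_model(cfg, steps = 8000, burn_in = 500, seed = 85)
  st <- analyze_run(run, n_surrogate = 60, seed = 86)
  expect_lt(st$corr_e, 0)
  expect_true(is.finite(st$corr_i))
  expect_gte(st$r_eplus, 0)
  expect_s3_class(st$fit_total, "power_law_fit")
  expect_gt(st$switching, 0)
})
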