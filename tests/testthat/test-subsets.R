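test_that("correlation spectrum ranks duplicates first and negations last", {
  set.seed(50)
  x <- rnorm(400)
  act <- rbind(x, x + rnorm(400, 0, 0.5), rnorm(400), -x, x)
  spec <- correlation_spectrum(act, seed_id = 1)
  expect_equal(spec$neuron[1], 5)           # exact duplicate
  expect_equal(spec$r[1], 1)
  expect_equal(spec$neuron[nrow(spec)], 4)  # exact negation
  expect_equal(spec$r[nrow(spec)], -1)

  # brute-force oracle on a toy matrix
  act2 <- matrix(rnorm(5 * 100), 5)
  spec2 <- correlation_spectrum(act2, 3)
  ref <- sapply(setdiff(1:5, 3), function(i) cor(act2[3, ], act2[i, ]))
  expect_equal(sort(spec2$r, decreasing = TRUE), sort(ref, decreasing = TRUE))

  act3 <- rbind(x, rep(1, 400), rnorm(400))
  expect_warning(s3 <- correlation_spectrum(act3, 1), "constant")
  expect_equal(s3$r[s3$neuron == 2], 0)
})

test_that("subsets recover planted structure and cancel by construction", {
  set.seed(51)
  lat <- rnorm(600)
  block <- t(vapply(1:60, function(i) lat + rnorm(600, 0, 0.4),
                    numeric(600)))
  noise <- matrix(rnorm(40 * 600), 40)
  act <- rbind(block, noise)
  sub <- build_subset(act, seed_id = 5, k = 50)
  expect_length(sub$member_ids, 50)
  expect_true(all(sub$member_ids <= 60))
  expect_false(5 %in% sub$member_ids)

  # canceling mode on x and -x copies averages to zero
  x <- rnorm(500)
  copies <- rbind(t(vapply(1:10, function(i) x, numeric(500))),
                  t(vapply(1:10, function(i) -x, numeric(500))))
  sub2 <- build_subset(copies, seed_id = 1, k = 10, mode = "canceling")
  expect_lt(max(abs(sub2$series$values)), 1e-10)

  # k = all others reduces to the z-scored population mean minus the seed
  small <- matrix(rnorm(6 * 200), 6)
  sub3 <- build_subset(small, 2, k = 5)
  z <- t(apply(small[-2, ], 1, function(v) (v - mean(v)) /
                 sqrt(mean((v - mean(v))^2))))
  expect_equal(sub3$series$values, colMeans(z))

  expect_error(build_subset(small, 1, k = 6), "smaller")
  expect_error(build_subset(small, 1, k = 3, mode = "canceling"), "even")
})

test_that("cyclic shifts preserve single-row statistics and break timing", {
  set.seed(52)
  act <- matrix(rnorm(8 * 1500), 8)
  surr <- time_shift_surrogate(act, seed = 53)
  for (i in 1:8) expect_equal(sort(surr[i, ]), sort(act[i, ]))

  # identical rows decorrelate after independent shifts
  x <- rnorm(2000)
  two <- rbind(x, x)
  hits <- sum(replicate(20, {
    s <- time_shift_surrogate(two)
    abs(cor(s[1, ], s[2, ])) < 3 / sqrt(2000)
  }))
  expect_gte(hits, 15)
})

test_that("shotgun search composes build, extract and fit per seed", {
  pp <- planted_fixture()
  act <- planted_preprocessed()[c(1:12, 151:162), ]  # groupA + noise neurons
  res <- shotgun_search(act, behaviors = pp$behaviors, n_seeds = 2, k = 8,
                        dt = 1 / 3, n_surrogate = 60, seed = 54)
  expect_equal(nrow(res$real), 2)
  expect_true("cor_behavior" %in% names(res$real))
  expect_equal(nrow(res$surrogate), 2)
  # table rows are consistent with the retained subset objects
  expect_equal(res$real$r[1], res$subsets[[1]]$fit$range_decades)
  expect_equal(res$real$seed_id[1], res$subsets[[1]]$seed_id)
  # membership is deterministic given the activity and the seed neuron
  again <- build_subset(act, res$real$seed_id[1], k = 8)
  expect_equal(res$subsets[[1]]$member_ids, again$member_ids)

  expect_error(shotgun_search(act, n_seeds = 100, k = 5), "exceeds")
})

test_that("behaviorally coupled subsets have larger range and correlation", {
  pp <- planted_fixture()
  res <- shotgun_search(planted_preprocessed(), behaviors = pp$behaviors,
                        n_seeds = 16, k = 50, dt = 1 / 3, n_surrogate = 100,
                        with_surrogate = FALSE, seed = 55)
  tab <- res$real
  big <- tab$r > 2.5
  none <- tab$r < 1
  expect_gt(sum(big), 0)
  expect_gt(sum(none), 0)
  # the testable core of the range-correlation relationship
  expect_gt(mean(tab$cor_behavior[big]), mean(tab$cor_behavior[none]))
})

test_that("canceling subsets lose power-law range relative to correlated ones", {
  act <- planted_preprocessed()
  seeds <- c(3, 17, 40)  # groupA seed neurons
  r_of <- function(mode, sd) {
    sub <- build_subset(act, sd, k = 50, mode = mode, dt = 1 / 3)
    ev <- extract_events(sub$series)
    fit_power_law_range(ev$size, n_surrogate = 100, seed = 56)$range_decades
  }
  for (sd in seeds) {
    expect_lt(r_of("canceling", sd) + 0.5, r_of("correlated", sd))
  }
})
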