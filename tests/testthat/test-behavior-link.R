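make_link <- function(significant) {
  structure(list(per_event = data.frame(event = seq_along(significant),
                                        n_samples = 5,
                                        n_strong = ifelse(significant, 9, 0),
                                        significant = significant,
                                        skipped = FALSE)),
            class = "event_link_result")
}

test_that("a subset identical to the behavior is strong for every event", {
  sizes <- sample_truncated_powerlaw(40, 1.4, 0.5, 50, seed = 60)
  beh <- make_event_series(sizes, dt = 1, seed = 61)
  ev <- extract_events(beh)
  set.seed(62)
  subs <- c(list(beh$values),
            lapply(1:9, function(i) rnorm(length(beh$values))))
  link <- event_specific_correlations(beh, ev, subs, n_controls = 100,
                                      seed = 63)
  ok <- !link$per_event$skipped
  expect_true(any(ok))
  expect_true(all(link$per_event$n_strong[ok] >= 1))
  expect_equal(nrow(link$per_subset), 10)
  expect_gte(link$per_subset$n_strong_events[1], sum(ok) - 1)
})

test_that("decoupled subsets rarely reach significance", {
  sizes <- sample_truncated_powerlaw(60, 1.4, 0.5, 50, seed = 64)
  beh <- make_event_series(sizes, dt = 1, seed = 65)
  ev <- extract_events(beh)
  set.seed(66)
  subs <- lapply(1:50, function(i) rnorm(length(beh$values)))
  link <- event_specific_correlations(beh, ev, subs, n_controls = 100,
                                      seed = 67)
  ok <- !link$per_event$skipped
  expect_lte(mean(link$per_event$significant[ok]), 0.05)
})

test_that("results are invariant to adding a constant to the behavior", {
  sizes <- sample_truncated_powerlaw(30, 1.4, 0.5, 20, seed = 68)
  beh <- make_event_series(sizes, dt = 1, seed = 69)
  ev <- extract_events(beh)
  set.seed(70)
  subs <- lapply(1:5, function(i) rnorm(length(beh$values)))
  l1 <- event_specific_correlations(beh$values, ev, subs, n_controls = 100,
                                    seed = 71)
  l2 <- event_specific_correlations(beh$values + 5, ev, subs,
                                    n_controls = 100, seed = 71)
  expect_equal(l1$per_event$n_strong, l2$per_event$n_strong)
})

test_that("active time fraction weighs events by duration", {
  v <- c(0, 2, 2, 0, 2, 2, 2, 0, 2, 2, 2, 2, 2, 0)
  ev <- extract_events(v, threshold = 1)  # durations 2, 3, 5
  expect_equal(ev$duration, c(2, 3, 5))
  expect_equal(active_time_fraction(ev, make_link(c(FALSE, FALSE, TRUE))), 0.5)
  expect_equal(active_time_fraction(ev, make_link(rep(TRUE, 3))), 1.0)
  expect_equal(active_time_fraction(ev, make_link(rep(FALSE, 3))), 0.0)
  empty <- extract_events(rep(0, 10), threshold = 1)
  expect_error(active_time_fraction(empty, make_link(logical(0))), "empty")
})

test_that("degenerate inputs are rejected or skipped", {
  beh <- make_event_series(c(2, 3), dt = 1, seed = 72)
  ev <- extract_events(beh)
  subs <- list(rnorm(length(beh$values)))
  expect_error(event_specific_correlations(beh, ev, subs, n_controls = 50),
               "n_controls")
  expect_error(event_specific_correlations(beh$values[1:10], ev, subs),
               "same length")
})
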