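#' Correlation spectrum of a seed neuron
#'
#' Pearson correlation of every other neuron's trace with the seed
#' neuron's, ranked in descending order (ties broken by neuron index).
#' Constant traces correlate with nothing; their coefficient is set to 0
#' with a warning.
#'
#' @param activity neurons x time numeric matrix (rows are neurons),
#'   normally preprocessed with [preprocess_activity()].
#' @param seed_id row index of the seed neuron.
#' @return Data frame with columns `neuron` and `r`, one row per non-seed
#'   neuron, sorted by descending `r`.
#' @export
correlation_spectrum <- function(activity, seed_id) {
  activity <- as.matrix(activity)
  n <- nrow(activity)
  if (n < 2) stop("need at least 2 neurons")
  if (seed_id < 1 || seed_id > n) stop("'seed_id' out of range")
  seed_tr <- activity[seed_id, ]
  if (sd(seed_tr) == 0) stop("seed neuron has a constant trace")
  others <- setdiff(seq_len(n), seed_id)
  sds <- apply(activity[others, , drop = FALSE], 1, sd)
  r <- rep(0, length(others))
  ok <- sds > 0
  if (any(!ok)) warning(sum(!ok), " constant neuron trace(s); correlation set to 0")
  if (any(ok))
    r[ok] <- as.numeric(cor(seed_tr, t(activity[others[ok], , drop = FALSE])))
  ord <- order(-r, others)
  data.frame(neuron = others[ord], r = r[ord])
}

#' Build a correlated or canceling neuron subset around a seed
#'
#' Correlated mode takes the `k` neurons most correlated with the seed
#' (seed excluded by default); canceling mode takes the `k/2` most
#' correlated plus the `k/2` most anticorrelated, the construction that
#' makes anticorrelated groups cancel in the average. The subset series is
#' the per-time mean of the members' z-scored traces.
#'
#' @param activity neurons x time matrix.
#' @param seed_id seed neuron row index.
#' @param k subset size (default 50; must be even in canceling mode).
#' @param mode `"correlated"` or `"canceling"`.
#' @param include_seed if `TRUE`, the seed is a member and `k - 1` neighbours
#'   are added.
#' @param dt sampling interval for the subset series.
#' @return A `subset_result`: list with `seed_id`, `member_ids`, `series`
#'   (a [time_series]), `spectrum`, and slots `fit`, `behavior_corr` filled
#'   by [shotgun_search()].
#' @export
build_subset <- function(activity, seed_id, k = 50,
                         mode = c("correlated", "canceling"),
                         include_seed = FALSE, dt = 1) {
  mode <- match.arg(mode)
  activity <- as.matrix(activity)
  if (k >= nrow(activity)) stop("'k' must be smaller than the number of neurons")
  spec <- correlation_spectrum(activity, seed_id)
  k_pick <- if (include_seed) k - 1 else k
  members <- if (mode == "correlated") {
    spec$neuron[seq_len(k_pick)]
  } else {
    if (k_pick %% 2 != 0) stop("canceling mode needs an even number of picks")
    c(spec$neuron[seq_len(k_pick / 2)],
      spec$neuron[seq(nrow(spec) - k_pick / 2 + 1, nrow(spec))])
  }
  if (include_seed) members <- c(seed_id, members)
  z <- t(apply(activity[members, , drop = FALSE], 1, function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  series <- time_series(colMeans(z), dt = dt,
                        label = sprintf("subset[seed %d, k %d, %s]",
                                        seed_id, k, mode))
  structure(list(seed_id = seed_id, member_ids = members, series = series,
                 spectrum = spec, fit = NULL, behavior_corr = NULL),
            class = "subset_result")
}

#' Cyclic time-shift surrogate of an activity matrix
#'
#' Each neuron's time series is independently rotated by a uniform random
#' number of samples in `[0, T)`: sample `i` becomes sample `i + N` (mod T).
#' Single-neuron statistics are preserved exactly while cross-neuron timing
#' is destroyed, so any correlation structure that survives is chance.
#'
#' @param activity neurons x time matrix.
#' @param seed optional RNG seed.
#' @return Matrix of the same dimensions.
#' @export
time_shift_surrogate <- function(activity, seed = NULL) {
  activity <- as.matrix(activity)
  nt <- ncol(activity)
  with_seed(seed, {
    shifts <- sample.int(nt, nrow(activity), replace = TRUE) - 1L
    out <- activity
    for (i in seq_len(nrow(activity))) {
      if (shifts[i] > 0) {
        out[i, ] <- c(activity[i, (nt - shifts[i] + 1):nt],
                      activity[i, 1:(nt - shifts[i])])
      }
    }
    out
  })
}

#' Shotgun search for scale-free neuron subsets
#'
#' Repeats, for randomly chosen seed neurons: build the subset of the `k`
#' neurons most correlated with the seed ([build_subset()]), extract
#' median-threshold events from the subset mean ([extract_events()]), fit
#' the event-size power-law range ([fit_power_law_range()]), and correlate
#' the subset series with each behavior channel. The identical pipeline is
#' then run on one cyclic time-shift surrogate of the activity matrix
#' ([time_shift_surrogate()]), giving the chance-level distribution of
#' power-law ranges.
#'
#' @param activity neurons x time matrix (preprocessed).
#' @param behaviors optional named list of [time_series] (or numeric
#'   vectors) to correlate each subset with.
#' @param n_seeds number of seed neurons, drawn uniformly without
#'   replacement.
#' @param k subset size.
#' @param mode subset construction mode, see [build_subset()].
#' @param dt sampling interval of the activity rows.
#' @param with_surrogate if `TRUE` (default) run the matched surrogate
#'   search.
#' @param F_criterion,n_surrogate,gap_frac fitting parameters, see
#'   [fit_power_law_range()].
#' @param include_seed see [build_subset()].
#' @param seed optional RNG seed governing seed choice, surrogate shifts and
#'   fitting surrogates.
#' @return List with data frames `real` and (if requested) `surrogate`, one
#'   row per seed: `seed_id`, `r` (range in decades), `tau`, `F`, `n_events`,
#'   and one `cor_<label>` column per behavior; plus `subsets`, the list of
#'   `subset_result` objects for the real data.
#' @export
shotgun_search <- function(activity, behaviors = NULL, n_seeds = 100, k = 50,
                           mode = "correlated", dt = 1, with_surrogate = TRUE,
                           F_criterion = 0.80, n_surrogate = 500,
                           gap_frac = 0.03, include_seed = FALSE,
                           seed = NULL) {
  activity <- as.matrix(activity)
  if (n_seeds > nrow(activity))
    stop("'n_seeds' exceeds the number of neurons")
  with_seed(seed, {
    seeds <- sample.int(nrow(activity), n_seeds)
    run_one <- function(mat, keep_subsets) {
      subsets <- vector("list", n_seeds)
      rows <- vector("list", n_seeds)
      for (i in seq_len(n_seeds)) {
        sub <- build_subset(mat, seeds[i], k = k, mode = mode,
                            include_seed = include_seed, dt = dt)
        ev <- extract_events(sub$series)
        fit <- if (nrow(ev) >= 3) {
          fit_power_law_range(ev$size, F_criterion = F_criterion,
                              gap_frac = gap_frac, n_surrogate = n_surrogate)
        } else {
          fit_power_law_range(c(1, 1, 1))  # degenerate: r = 0
        }
        sub$fit <- fit
        row <- data.frame(seed_id = seeds[i], r = fit$range_decades,
                          tau = fit$tau, F = fit$F, n_events = nrow(ev))
        if (!is.null(behaviors)) {
          bc <- vapply(behaviors, function(b)
            cor(sub$series$values, ts_values(b)), numeric(1))
          names(bc) <- paste0("cor_", names(behaviors))
          sub$behavior_corr <- bc
          row <- cbind(row, as.data.frame(as.list(bc)))
        }
        rows[[i]] <- row
        if (keep_subsets) subsets[[i]] <- sub
      }
      list(table = do.call(rbind, rows), subsets = subsets)
    }
    real <- run_one(activity, keep_subsets = TRUE)
    out <- list(real = real$table, subsets = real$subsets)
    if (with_surrogate) {
      surr_mat <- time_shift_surrogate(activity)
      out$surrogate <- run_one(surr_mat, keep_subsets = FALSE)$table
    }
    out
  })
}
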