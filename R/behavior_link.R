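#' Event-specific correlations between behavior and neural subsets
#'
#' For each behavioral event, correlates the behavior series with every
#' neural subset series over just that event's window, and compares each
#' real coefficient against `n_controls` chance-level coefficients obtained
#' from cyclically time-shifted subset series (shifts uniform over the
#' recording, one independently shifted subset copy per control). A subset
#' is "strongly correlated" with an event when its real coefficient exceeds
#' the `ceiling(0.999 * n_controls)`-th order statistic of that event's
#' controls (for 1000 controls: greater than 999 of them). An event is
#' significant when more than 4 subsets are strong -- the chance
#' expectation of the count is 1.
#'
#' Control coefficients cycle over the subsets (control `i` uses subset
#' `((i - 1) mod n_subsets) + 1` with a fresh random shift), so with as many
#' subsets as controls each subset contributes exactly one control per
#' event.
#'
#' @param behavior a [time_series] or numeric vector.
#' @param beh_events an `event_set` extracted from `behavior`.
#' @param subset_series list of [time_series]/numeric vectors, or a
#'   subsets x time matrix.
#' @param n_controls number of control coefficients per event (>= 100).
#' @param strong_count_threshold strong-subset count above which an event is
#'   significant (default 4).
#' @param seed optional RNG seed.
#' @return An `event_link_result`: list with `per_event` (data frame:
#'   `event`, `n_samples`, `n_strong`, `significant`, `skipped`),
#'   `per_subset` (data frame: `subset`, `n_strong_events`), and the control
#'   settings.
#' @export
event_specific_correlations <- function(behavior, beh_events, subset_series,
                                        n_controls = 1000,
                                        strong_count_threshold = 4,
                                        seed = NULL) {
  if (n_controls < 100) stop("'n_controls' must be at least 100")
  b <- ts_values(behavior)
  S <- if (is.matrix(subset_series)) subset_series
       else do.call(rbind, lapply(subset_series, ts_values))
  if (ncol(S) != length(b))
    stop("subset series and behavior must have the same length")
  ns <- nrow(S)
  nt <- length(b)
  ne <- nrow(beh_events)
  rank_idx <- ceiling(0.999 * n_controls)

  with_seed(seed, {
    n_strong <- integer(ne)
    skipped <- logical(ne)
    n_samples <- integer(ne)
    strong_mat <- matrix(FALSE, ne, ns)
    for (e in seq_len(ne)) {
      w <- beh_events$start[e]:beh_events$end[e]
      n_samples[e] <- length(w)
      if (length(w) < 3) {
        warning(sprintf("event %d window shorter than 3 samples; skipped", e))
        skipped[e] <- TRUE
        next
      }
      bw <- b[w]
      if (sd(bw) == 0) {
        skipped[e] <- TRUE
        next
      }
      real_r <- as.numeric(cor(bw, t(S[, w, drop = FALSE])))
      real_r[is.na(real_r)] <- -Inf  # constant subset window: never strong
      ctrl <- numeric(n_controls)
      for (i in seq_len(n_controls)) {
        j <- ((i - 1) %% ns) + 1
        sh <- sample.int(nt, 1) - 1L
        widx <- ((w - 1 + sh) %% nt) + 1
        sw <- S[j, widx]
        ctrl[i] <- if (sd(sw) == 0) -Inf else cor(bw, sw)
      }
      thr <- sort(ctrl, partial = rank_idx)[rank_idx]
      strong_mat[e, ] <- real_r > thr
      n_strong[e] <- sum(strong_mat[e, ])
    }
    per_event <- data.frame(event = seq_len(ne), n_samples = n_samples,
                            n_strong = n_strong,
                            significant = !skipped &
                              n_strong > strong_count_threshold,
                            skipped = skipped)
    per_subset <- data.frame(subset = seq_len(ns),
                             n_strong_events = colSums(strong_mat))
    structure(list(per_event = per_event, per_subset = per_subset,
                   n_controls = n_controls,
                   strong_count_threshold = strong_count_threshold),
              class = "event_link_result")
  })
}

#' Fraction of behaviorally active time with significant neural correlation
#'
#' The summed duration of the significant behavioral events divided by the
#' summed duration of all behavioral events.
#'
#' @param beh_events the `event_set` the link was computed on.
#' @param link an `event_link_result` from
#'   [event_specific_correlations()].
#' @return A fraction in `[0, 1]`.
#' @export
active_time_fraction <- function(beh_events, link) {
  if (nrow(beh_events) == 0) stop("empty event set")
  if (nrow(beh_events) != nrow(link$per_event))
    stop("'link' was not computed on 'beh_events'")
  sum(beh_events$duration[link$per_event$significant]) /
    sum(beh_events$duration)
}
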