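#' Duration-distribution exponent for events inside the size power-law range
#'
#' Restricts the events to those whose size lies inside the fitted size
#' range `[s_min, s_max]`, then fits their durations with the same truncated
#' maximum-likelihood machinery used for sizes, with the duration bounds
#' taken as the minimum and maximum of the filtered durations. Using the
#' same event population for sizes and durations keeps the exponents
#' tau, alpha and beta comparable.
#'
#' @param events an `event_set`.
#' @param size_fit a `power_law_fit` for the event sizes, with positive
#'   range.
#' @param tau_grid exponent search grid.
#' @param n_surrogate surrogates for the duration goodness-of-fit.
#' @param seed optional RNG seed.
#' @return List with `alpha`, `F_alpha`, `t_min`, `t_max`, `n`.
#' @export
duration_exponent <- function(events, size_fit,
                              tau_grid = seq(0.7, 2, by = 0.02),
                              n_surrogate = 500, seed = NULL) {
  if (!inherits(size_fit, "power_law_fit") || size_fit$range_decades <= 0)
    stop("'size_fit' must be a power_law_fit with positive range")
  ev <- events[events$size >= size_fit$s_min & events$size <= size_fit$s_max, ]
  durs <- ev$duration
  if (length(unique(durs)) < 2)
    stop("degenerate durations: all in-range events have the same duration")
  t_min <- min(durs); t_max <- max(durs)
  mle <- fit_truncated_mle(durs, t_min, t_max, tau_grid)
  Fv <- goodness_of_fit(durs, tau = mle$tau, s_min = t_min, s_max = t_max,
                        n_surrogate = n_surrogate, seed = seed)
  list(alpha = mle$tau, F_alpha = Fv, t_min = t_min, t_max = t_max,
       n = mle$n_tail)
}

#' Size-versus-duration scaling exponent
#'
#' Ordinary least-squares fit of `log10(size)` on `log10(duration)`; the
#' slope is the scaling exponent beta in `S(T) ~ T^beta`. By default the
#' regression uses the events inside the size power-law range when a
#' `size_fit` is supplied, matching the population used for tau and alpha;
#' pass `size_fit = NULL` to use all events.
#'
#' @param events an `event_set` (or data frame with `size` and `duration`).
#' @param size_fit optional `power_law_fit` restricting the events.
#' @return List with `beta`, `intercept`, `n`.
#' @export
size_vs_duration <- function(events, size_fit = NULL) {
  ev <- events
  if (!is.null(size_fit)) {
    if (size_fit$range_decades <= 0)
      stop("'size_fit' must have positive range (or be NULL)")
    ev <- ev[ev$size >= size_fit$s_min & ev$size <= size_fit$s_max, ]
  }
  if (nrow(ev) < 10) stop("need at least 10 events")
  if (length(unique(ev$duration)) < 2)
    stop("zero-variance regressor: all durations equal")
  fit <- lm(log10(size) ~ log10(duration), data = ev)
  list(beta = coef(fit)[[2]], intercept = coef(fit)[[1]], n = nrow(ev))
}

#' Crackling-noise prediction for the size-duration exponent
#'
#' The crackling-noise scaling relation links the three exponents of a
#' critical system: `beta = (alpha - 1) / (tau - 1)`. The prediction is
#' undefined when tau is at (or numerically near) 1, where the denominator
#' vanishes and the predicted value blows up or changes sign.
#'
#' @param tau size-distribution exponent.
#' @param alpha duration-distribution exponent.
#' @return The predicted beta.
#' @examples
#' crackling_prediction(tau = 1.5, alpha = 1.5)  # 1
#' @export
crackling_prediction <- function(tau, alpha) {
  if (abs(tau - 1) <= 1e-6)
    stop("crackling prediction undefined: tau is numerically 1")
  (alpha - 1) / (tau - 1)
}

#' All three scaling exponents of an event set
#'
#' Convenience wrapper combining the size fit, [duration_exponent()] and
#' [size_vs_duration()], plus the crackling-noise prediction where defined.
#'
#' @param events an `event_set`.
#' @param size_fit a `power_law_fit` for the sizes; if `NULL` it is computed
#'   here.
#' @param ... passed to [fit_power_law_range()] when `size_fit` is `NULL`.
#' @param n_surrogate surrogates for the duration goodness-of-fit.
#' @param seed optional RNG seed.
#' @return List with `tau`, `alpha`, `beta_fit`, `beta_crackling` (`NA` when
#'   tau is near 1 or the size fit failed), `n_events`.
#' @export
scaling_exponents <- function(events, size_fit = NULL, n_surrogate = 500,
                              seed = NULL, ...) {
  if (is.null(size_fit))
    size_fit <- fit_power_law_range(events$size, n_surrogate = n_surrogate,
                                    seed = seed, ...)
  if (size_fit$range_decades <= 0) {
    return(list(tau = NA_real_, alpha = NA_real_, beta_fit = NA_real_,
                beta_crackling = NA_real_, n_events = nrow(events),
                size_fit = size_fit))
  }
  dur <- duration_exponent(events, size_fit, n_surrogate = n_surrogate,
                           seed = seed)
  sv <- size_vs_duration(events, size_fit)
  bc <- if (abs(size_fit$tau - 1) > 1e-6)
    crackling_prediction(size_fit$tau, dur$alpha) else NA_real_
  list(tau = size_fit$tau, alpha = dur$alpha, beta_fit = sv$beta,
       beta_crackling = bc, n_events = nrow(events), size_fit = size_fit,
       F_alpha = dur$F_alpha)
}
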