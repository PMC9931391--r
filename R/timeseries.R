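#' Uniformly sampled time series
#'
#' Light container for one real-valued channel: a numeric vector plus the
#' sampling interval `dt` (seconds per sample) and a label. All event and
#' subset machinery in this package operates on these objects (or on plain
#' numeric vectors, in which case `dt = 1` is assumed).
#'
#' @param values numeric vector, finite, length at least 2.
#' @param dt sampling interval in seconds per sample (> 0).
#' @param label channel name.
#' @return An object of class `time_series`: a list with elements `values`,
#'   `dt`, `label`.
#' @examples
#' ts <- time_series(sin(seq(0, 10, by = 0.1)), dt = 0.1, label = "toy")
#' ts
#' @export
time_series <- function(values, dt = 1, label = "") {
  values <- as.numeric(values)
  if (length(values) < 2) stop("time series must have length >= 2")
  if (!all(is.finite(values))) stop("time series values must be finite")
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number")
  structure(list(values = values, dt = dt, label = as.character(label)[1]),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> '%s': %d samples, dt = %g s (%.1f s total)\n",
              x$label, length(x$values), x$dt, length(x$values) * x$dt))
  invisible(x)
}

# coerce numeric or time_series input; returns time_series
as_time_series <- function(x, dt = 1, label = "") {
  if (inherits(x, "time_series")) return(x)
  time_series(x, dt = dt, label = label)
}

ts_values <- function(x) if (inherits(x, "time_series")) x$values else as.numeric(x)
ts_dt     <- function(x) if (inherits(x, "time_series")) x$dt else 1

# apply f to the values, preserving the container type of the input
map_values <- function(x, f) {
  if (inherits(x, "time_series")) {
    x$values <- f(x$values)
    x
  } else {
    f(as.numeric(x))
  }
}

#' Z-score a time series (population convention)
#'
#' Subtracts the mean and divides by the population standard deviation
#' (divisor n, not n - 1). Constant input is an error: there is no scale to
#' normalize by.
#'
#' @param x a [time_series] or numeric vector.
#' @return Same type as the input, with mean 0 and population SD 1.
#' @examples
#' zscore(c(0, 2))   # -1, 1
#' @export
zscore <- function(x) {
  map_values(x, function(v) {
    mu <- mean(v)
    s <- sqrt(mean((v - mu)^2))
    if (!is.finite(s) || s == 0) stop("cannot z-score a series with zero variance")
    (v - mu) / s
  })
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and backward
#' (forward-backward filtering), so the result has zero phase distortion and
#' an effective magnitude response equal to the squared single-pass response
#' (amplitude 1/2 at the cutoff frequency). Edges are handled by odd
#' (point-reflected) padding of length `3 * (order + 1)` samples, the
#' standard practice for forward-backward filters.
#'
#' @param x a [time_series], or numeric vector with sampling interval `dt`.
#' @param cutoff_hz cutoff frequency in Hz; must lie strictly between 0 and
#'   the Nyquist frequency `1 / (2 * dt)`.
#' @param order filter order (default 2).
#' @param dt sampling interval, used when `x` is a plain vector.
#' @return Filtered series of the same type and length as the input.
#' @export
lowpass_zero_phase <- function(x, cutoff_hz, order = 2, dt = ts_dt(x)) {
  if (!is.numeric(order) || order < 1) stop("'order' must be >= 1")
  nyq <- 1 / (2 * dt)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop(sprintf("'cutoff_hz' must lie in (0, Nyquist = %g Hz)", nyq))
  flt <- signal::butter(order, W = cutoff_hz / nyq, type = "low")
  map_values(x, function(v) {
    n <- length(v)
    pad <- min(3 * (order + 1), n - 1)
    vp <- c(2 * v[1] - v[(pad + 1):2],
            v,
            2 * v[n] - v[(n - 1):(n - pad)])
    # subtracting the leading value before each pass initializes the filter
    # at its DC steady state (unit passband gain), so constants pass exactly
    one_pass <- function(z) {
      as.numeric(signal::filter(flt, z - z[1])) + z[1]
    }
    y <- one_pass(vp)
    y <- rev(one_pass(rev(y)))
    as.numeric(y[(pad + 1):(pad + n)])
  })
}

#' Standard conditioning of neural activity traces
#'
#' Per-neuron z-scoring followed by zero-phase low-pass filtering (0.2 Hz
#' cutoff, 2nd-order Butterworth by default), the conditioning applied to
#' deconvolved calcium traces before event analysis. Behavioral series are
#' conventionally left raw. The order (z-score, then filter) can be swapped
#' with `filter_first = TRUE`.
#'
#' @param activity neurons x time numeric matrix.
#' @param dt sampling interval in seconds (default `1/3`, i.e. 3 Hz frames).
#' @param cutoff_hz low-pass cutoff in Hz.
#' @param order Butterworth order.
#' @param filter_first if `TRUE`, filter before z-scoring.
#' @return Matrix of the same dimensions, conditioned row by row.
#' @export
preprocess_activity <- function(activity, dt = 1 / 3, cutoff_hz = 0.2,
                                order = 2, filter_first = FALSE) {
  activity <- as.matrix(activity)
  out <- t(apply(activity, 1, function(v) {
    if (filter_first) {
      zscore(lowpass_zero_phase(v, cutoff_hz, order = order, dt = dt))
    } else {
      lowpass_zero_phase(zscore(v), cutoff_hz, order = order, dt = dt)
    }
  }))
  dimnames(out) <- dimnames(activity)
  out
}
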