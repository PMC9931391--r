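#' Extract suprathreshold events from a time series
#'
#' An event is a maximal run of samples strictly above the threshold; it
#' begins when the series exceeds the threshold and ends when it returns to
#' or below it. The event size is the area between the series and the
#' threshold over the run (rectangle rule, `dt * sum(value - threshold)`),
#' and the duration is `dt` times the run length. Runs touching either
#' boundary of the recording are kept; numerically zero-area events are
#' dropped. With the default threshold, the median of the entire series, a
#' constant series yields zero events.
#'
#' @param x a [time_series] or numeric vector.
#' @param threshold `"median"` (default) or a numeric threshold on the same
#'   scale as the series.
#' @param dt sampling interval, used when `x` is a plain vector.
#' @param integration `"rectangle"` (default) or `"trapezoid"` area rule.
#' @return An `event_set`: a data frame with columns `start`, `end` (sample
#'   indices), `start_s`, `end_s` (seconds), `size`, `duration`, carrying the
#'   resolved threshold, `dt` and source label as attributes. Zero rows when
#'   nothing exceeds the threshold.
#' @examples
#' extract_events(c(0, 1, 1, 0, 2, 0), threshold = 0.5)
#' @export
extract_events <- function(x, threshold = "median", dt = ts_dt(x),
                           integration = c("rectangle", "trapezoid")) {
  integration <- match.arg(integration)
  v <- ts_values(x)
  if (!all(is.finite(v))) stop("series must be finite")
  label <- if (inherits(x, "time_series")) x$label else ""
  thr <- if (identical(threshold, "median")) median(v) else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    threshold
  }

  above <- v > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]

  if (length(starts)) {
    size <- vapply(seq_along(starts), function(i) {
      seg <- v[starts[i]:ends[i]] - thr
      if (integration == "rectangle") dt * sum(seg)
      else dt * (sum(seg) - (seg[1] + seg[length(seg)]) / 2)
    }, numeric(1))
    duration <- (ends - starts + 1) * dt
    ok <- size > 0
    starts <- starts[ok]; ends <- ends[ok]
    size <- size[ok]; duration <- duration[ok]
  } else {
    size <- duration <- numeric(0)
  }

  out <- data.frame(start = starts, end = ends,
                    start_s = (starts - 1) * dt, end_s = ends * dt,
                    size = size, duration = duration)
  structure(out, class = c("event_set", "data.frame"),
            threshold = thr, dt = dt, source_label = label)
}

#' Write an event set to CSV
#'
#' Columns `start_s`, `end_s`, `size`, `duration`.
#'
#' @param events an `event_set` from [extract_events()].
#' @param path output file path.
#' @export
write_events <- function(events, path) {
  write.csv(events[, c("start_s", "end_s", "size", "duration")],
            path, row.names = FALSE)
  invisible(path)
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d events (threshold %.4g, dt %g s)\n",
              nrow(x), attr(x, "threshold"), attr(x, "dt")))
  if (nrow(x)) {
    cat(sprintf("  sizes %.3g .. %.3g, durations %.3g .. %.3g s\n",
                min(x$size), max(x$size), min(x$duration), max(x$duration)))
  }
  invisible(x)
}
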