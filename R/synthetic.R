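#' Sample from a truncated power law
#'
#' Inverse-CDF sampling of the continuous truncated power law on
#' `[s_min, s_max]`: for tau != 1,
#' `s = (s_min^(1-tau) + u (s_max^(1-tau) - s_min^(1-tau)))^(1/(1-tau))`,
#' and for tau = 1, `s = s_min (s_max/s_min)^u`, with u uniform on (0, 1).
#'
#' @param n number of samples (>= 1).
#' @param tau exponent.
#' @param s_min,s_max truncation bounds, `0 < s_min < s_max`.
#' @param seed optional RNG seed.
#' @return Numeric vector of n sizes in `[s_min, s_max]`.
#' @examples
#' s <- sample_truncated_powerlaw(1000, 1.5, 1, 1e3, seed = 1)
#' range(s)
#' @export
sample_truncated_powerlaw <- function(n, tau, s_min, s_max, seed = NULL) {
  if (n < 1) stop("'n' must be at least 1")
  if (!(s_min > 0 && s_min < s_max)) stop("need 0 < s_min < s_max")
  with_seed(seed, rtruncpl(n, tau, s_min, s_max))
}

#' Build a bursty series whose events have prescribed sizes
#'
#' Places one half-sine bump per requested size on a zero baseline, with
#' positive inter-event gaps long enough that more than half of all samples
#' sit at the baseline -- so the series median is exactly 0 and
#' [extract_events()] with the default median threshold recovers one event
#' per bump with its prescribed area. Bump durations scale with size as
#' `T ~ s^(1/shape_beta)`, so sizes and durations are coupled through a
#' tunable power law; each amplitude is then solved exactly from the
#' requested area.
#'
#' @param event_sizes positive event sizes (areas, in value x seconds).
#' @param dt sampling interval.
#' @param shape_beta exponent coupling duration to size (default 2:
#'   `s ~ T^2`).
#' @param gap_factor mean gap length as a multiple of the preceding event
#'   length (default 2; must keep the baseline in the majority).
#' @param seed optional RNG seed for the gap lengths.
#' @return A [time_series] with attribute `event_table` (data frame:
#'   `start`, `length`, `size`) recording the planted events.
#' @export
make_event_series <- function(event_sizes, dt = 1, shape_beta = 2,
                              gap_factor = 2, seed = NULL) {
  if (length(event_sizes) && any(event_sizes <= 0))
    stop("event sizes must be positive")
  if (gap_factor <= 1) stop("'gap_factor' must exceed 1 to keep the median at baseline")
  if (length(event_sizes) == 0) {
    return(structure(time_series(rep(0, 100), dt = dt, label = "synthetic"),
                     event_table = data.frame(start = integer(0),
                                              length = integer(0),
                                              size = numeric(0))))
  }
  s_ref <- min(event_sizes)
  lens <- pmax(3L, as.integer(round(3 * (event_sizes / s_ref)^(1 / shape_beta))))
  with_seed(seed, {
    gaps <- pmax(2L, as.integer(ceiling(lens * gap_factor * (0.6 + rexp(length(lens))))))
    pieces <- vector("list", 2 * length(lens) + 1)
    pieces[[1]] <- rep(0, gaps[1])
    starts <- integer(length(lens))
    pos <- gaps[1]
    for (i in seq_along(lens)) {
      bump <- sin(pi * seq_len(lens[i]) / (lens[i] + 1))
      bump <- bump * event_sizes[i] / (dt * sum(bump))  # exact area
      pieces[[2 * i]] <- bump
      starts[i] <- pos + 1L
      pos <- pos + lens[i]
      pieces[[2 * i + 1]] <- rep(0, gaps[min(i + 1, length(gaps))])
      pos <- pos + length(pieces[[2 * i + 1]])
    }
    v <- unlist(pieces)
    if (sum(v == 0) <= length(v) / 2)
      stop("gaps too short: baseline must hold the majority of samples")
    structure(time_series(v, dt = dt, label = "synthetic"),
              event_table = data.frame(start = starts, length = lens,
                                       size = event_sizes))
  })
}

# rebuild a series from an event table with per-event amplitude factors
rebuild_event_series <- function(ts, amp_factors) {
  tab <- attr(ts, "event_table")
  v <- rep(0, length(ts$values))
  for (i in seq_len(nrow(tab))) {
    idx <- tab$start[i]:(tab$start[i] + tab$length[i] - 1)
    v[idx] <- ts$values[idx] * amp_factors[i]
  }
  time_series(v, dt = ts$dt, label = paste0(ts$label, "-jittered"))
}

#' Synthetic population with planted anticorrelated scale-free structure
#'
#' Generates the structure the subset analysis assumes so that every
#' pipeline stage has ground truth: a scale-free latent driver A (bursty
#' series whose event areas follow a truncated power law), an anti-phase
#' counterpart B (the rectified complement of A, anticorrelated with A by
#' construction), a group of neurons coupled to each driver plus Gaussian
#' noise, uncorrelated pure-noise neurons, and one behavior channel that
#' shares A's event times but with independent per-event amplitude jitter.
#' Because the two groups fluctuate in anti-phase, their contributions
#' cancel in the whole-population average.
#'
#' @param n_neurons total neuron count.
#' @param group_sizes named vector `c(groupA = ..., groupB = ...)`; the
#'   remainder are noise neurons.
#' @param t_samples recording length in samples.
#' @param dt sampling interval in seconds (default 1/3: 3 Hz frames).
#' @param tau,s_min,s_max truncated power law of the planted event sizes.
#' @param coupling multiplicative coupling of group neurons to their driver
#'   (> 0).
#' @param noise_sd per-neuron Gaussian noise SD, in units of the driver's
#'   SD (default 2: single neurons are noise-dominated, as in calcium
#'   imaging, so the scale-free structure emerges only in correlated
#'   averages and is destroyed by time-shift surrogates -- the structure
#'   the subset analysis assumes).
#' @param behavior_jitter_sd SD of the lognormal per-event amplitude jitter
#'   on the behavior channel (log10 scale, default 0.15).
#' @param seed optional RNG seed; the whole object is bit-reproducible
#'   given the seed.
#' @return A `planted_population`: list with `activity` (neurons x time),
#'   `membership` (factor: groupA/groupB/noise), `latent` (list of the two
#'   driver [time_series]), `behaviors` (named list with `behavior`), and
#'   `truth` (the generator parameters).
#' @export
make_planted_population <- function(n_neurons = 300,
                                    group_sizes = c(groupA = 100,
                                                    groupB = 100),
                                    t_samples = 10000, dt = 1 / 3,
                                    tau = 1.5, s_min = 0.01, s_max = 100,
                                    coupling = 1, noise_sd = 2,
                                    behavior_jitter_sd = 0.15,
                                    seed = NULL) {
  if (coupling <= 0) stop("'coupling' must be positive")
  n_noise <- n_neurons - sum(group_sizes)
  if (n_noise < 0) stop("group sizes exceed 'n_neurons'")
  with_seed(seed, {
    # draw events until the series covers t_samples, then trim
    latentA <- NULL
    n_ev <- max(20, round(t_samples / 40))
    repeat {
      sizes <- rtruncpl(n_ev, tau, s_min, s_max)
      latentA <- make_event_series(sizes, dt = dt)
      if (length(latentA$values) >= t_samples) break
      n_ev <- ceiling(n_ev * 1.5)
    }
    keep <- seq_len(t_samples)
    tab <- attr(latentA, "event_table")
    latentA <- structure(time_series(latentA$values[keep], dt = dt,
                                     label = "latentA"),
                         event_table = tab[tab$start + tab$length - 1 <=
                                             t_samples, ])
    if (sum(latentA$values == 0) <= t_samples / 2)
      stop("trimmed latent series lost its baseline majority; increase 't_samples'")
    a <- latentA$values
    m <- quantile(a[a > 0], 0.95)
    latentB <- time_series(pmax(m - a, 0), dt = dt, label = "latentB")

    sd_a <- sd(a)
    noise <- noise_sd * sd_a
    mk_group <- function(driver, n_rows) {
      t(vapply(seq_len(n_rows),
               function(i) coupling * driver + rnorm(t_samples, 0, noise),
               numeric(t_samples)))
    }
    activity <- rbind(
      mk_group(a, group_sizes[["groupA"]]),
      mk_group(latentB$values * (sd_a / sd(latentB$values)),
               group_sizes[["groupB"]]),
      if (n_noise > 0)
        matrix(rnorm(n_noise * t_samples, 0, coupling * sd_a), n_noise)
    )
    membership <- factor(rep(c("groupA", "groupB", "noise"),
                             c(group_sizes[["groupA"]],
                               group_sizes[["groupB"]], n_noise)),
                         levels = c("groupA", "groupB", "noise"))

    tabA <- attr(latentA, "event_table")
    jitter <- 10^rnorm(nrow(tabA), 0, behavior_jitter_sd)
    behavior <- rebuild_event_series(latentA, jitter)
    behavior$label <- "behavior"

    structure(list(activity = activity, membership = membership,
                   latent = list(A = latentA, B = latentB),
                   behaviors = list(behavior = behavior),
                   truth = list(tau = tau, s_min = s_min, s_max = s_max,
                                coupling = coupling, noise_sd = noise_sd,
                                dt = dt, seed = seed)),
              class = "planted_population")
  })
}
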