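GROUPS <- c("e+", "e-", "i+", "i-")

#' Canonical winner-take-all block-density matrix
#'
#' The reference wiring of the four-population model: dense (50%)
#' connectivity within each excitatory group, sparse (5%) connectivity
#' between them, and dense crossing inhibition -- e+ drives i+ which
#' suppresses e-, and e- drives i- which suppresses e+. All other blocks
#' are zero. Entry `[target, source]` is the connection density from the
#' source group to the target group.
#'
#' @param dense,sparse the two nonzero density levels (defaults 0.5, 0.05).
#' @return A 4x4 density matrix with dimnames `e+`, `e-`, `i+`, `i-`.
#' @export
canonical_density <- function(dense = 0.5, sparse = 0.05) {
  D <- matrix(0, 4, 4, dimnames = list(GROUPS, GROUPS))
  D["e+", "e+"] <- dense
  D["e-", "e-"] <- dense
  D["e+", "e-"] <- sparse
  D["e-", "e+"] <- sparse
  D["i+", "e+"] <- dense  # e+ -> i+
  D["e-", "i+"] <- dense  # i+ -| e-
  D["i-", "e-"] <- dense  # e- -> i-
  D["e+", "i-"] <- dense  # i- -| e+
  D
}

#' Configuration of the four-population binary network
#'
#' Groups are, in order, the two excitatory populations `e+` and `e-`
#' (400 neurons each by default) and the two inhibitory populations `i+`
#' and `i-` (100 each). `density` maps each ordered (target, source) group
#' pair to a connection density in `{0, 0.05, 0.5}`. `Lambda` is the target
#' largest eigenvalue of the realized connectivity matrix (1 = the critical
#' operating point); `eta` is the uniform external drive added to every
#' neuron's input each step.
#'
#' @param group_sizes named integer vector of the four group sizes.
#' @param density 4x4 density matrix, `[target, source]`.
#' @param Lambda target largest eigenvalue (> 0).
#' @param eta external drive (>= 0); default 0.05, mid-range of the drive
#'   sweep over which the model reproduces the experimental signature.
#' @param excitatory logical vector marking which groups are excitatory
#'   (sources with positive weights).
#' @return A `network_config`.
#' @export
network_config <- function(group_sizes = c("e+" = 400, "e-" = 400,
                                           "i+" = 100, "i-" = 100),
                           density = canonical_density(), Lambda = 1,
                           eta = 0.05,
                           excitatory = c(TRUE, TRUE, FALSE, FALSE)) {
  stopifnot(length(group_sizes) == 4, all(group_sizes > 0))
  density <- as.matrix(density)
  stopifnot(dim(density) == c(4, 4))
  if (!all(density %in% c(0, 0.05, 0.5)))
    stop("densities must be 0, 0.05 or 0.5")
  if (!is.numeric(Lambda) || Lambda <= 0) stop("'Lambda' must be positive")
  if (!is.numeric(eta) || eta < 0) stop("'eta' must be non-negative")
  structure(list(group_sizes = group_sizes, density = density,
                 Lambda = Lambda, eta = eta, excitatory = excitatory),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> N = %d (%s), Lambda = %g, eta = %g\n",
              sum(x$group_sizes),
              paste(names(x$group_sizes), x$group_sizes, sep = ":",
                    collapse = " "),
              x$Lambda, x$eta))
  print(x$density)
  invisible(x)
}

# group index (0-based for the C++ core) of each neuron
group_index <- function(config) rep(0:3, config$group_sizes)

#' Realize the connectivity matrix of a network configuration
#'
#' Draws a Bernoulli mask per block at the block's density, assigns weight
#' +c to connections from excitatory groups and -c to connections from
#' inhibitory groups, zeroes the diagonal (no self-connections), and scales
#' the whole matrix so that its largest-magnitude eigenvalue equals
#' `Lambda`. The pre-normalization constant c is 1, so after scaling all
#' nonzero weights share a single magnitude.
#'
#' @param config a [network_config()].
#' @param seed optional RNG seed for the Bernoulli masks.
#' @return A sparse `dgCMatrix` W with `W[i, j]` the weight of the
#'   connection j -> i, carrying attributes `spectral_radius_raw` (the
#'   pre-scaling largest eigenvalue magnitude) and `Lambda`.
#' @export
build_connectivity <- function(config, seed = NULL) {
  gs <- config$group_sizes
  n <- sum(gs)
  bounds <- c(0, cumsum(gs))
  sgn <- ifelse(config$excitatory, 1, -1)
  with_seed(seed, {
    W <- matrix(0, n, n)
    for (tg in 1:4) {
      for (sg in 1:4) {
        d <- config$density[tg, sg]
        if (d > 0) {
          ti <- (bounds[tg] + 1):bounds[tg + 1]
          si <- (bounds[sg] + 1):bounds[sg + 1]
          W[ti, si] <- matrix(rbinom(length(ti) * length(si), 1, d),
                              length(ti)) * sgn[sg]
        }
      }
    }
    diag(W) <- 0
    sr <- max(Mod(eigen(W, only.values = TRUE)$values))
    if (sr == 0) stop("all-zero connectivity: spectral radius is 0")
    Ws <- methods::as(methods::as(Matrix::Matrix(W * (config$Lambda / sr),
                                                 sparse = TRUE,
                                                 doDiag = FALSE),
                                  "generalMatrix"), "CsparseMatrix")
    attr(Ws, "spectral_radius_raw") <- sr
    attr(Ws, "Lambda") <- config$Lambda
    Ws
  })
}

#' Simulate the probabilistic binary network
#'
#' Synchronous update: each neuron fires at step t with probability equal
#' to `eta` plus the summed weighted input from the neurons active at
#' t - 1, clamped to `[0, 1]` ("fires in proportion to its input"). The
#' network starts all-quiescent and the first `burn_in` steps are
#' discarded. With a fixed seed the run is bit-reproducible.
#'
#' @param W connectivity matrix from [build_connectivity()] (or any sparse
#'   `dgCMatrix`).
#' @param eta external drive (>= 0).
#' @param steps number of recorded steps after burn-in.
#' @param burn_in discarded initial steps (default 1000).
#' @param groups integer group label per neuron (1..4), or a
#'   [network_config()] to derive them from.
#' @param keep_states if `TRUE` also return the full binary raster
#'   (memory O(N * steps)).
#' @param seed optional RNG seed.
#' @return A `model_run`: list with `group_means` (4 x steps matrix, rows
#'   named by group; per-neuron average within each group),
#'   `population_mean` (all-neuron average), `group_sizes`, `eta`, `steps`,
#'   and optionally `states`.
#' @export
simulate_network <- function(W, eta, steps, burn_in = 1000, groups,
                             keep_states = FALSE, seed = NULL) {
  if (eta < 0) stop("'eta' must be non-negative")
  if (steps <= 0 || burn_in < 0) stop("need steps > 0 and burn_in >= 0")
  if (inherits(groups, "network_config")) {
    gs <- groups$group_sizes
    grp <- group_index(groups)
  } else {
    grp <- as.integer(groups) - 1L
    gs <- as.integer(table(factor(grp, levels = 0:3)))
    names(gs) <- GROUPS
  }
  W <- methods::as(methods::as(W, "generalMatrix"), "CsparseMatrix")
  if (nrow(W) != length(grp)) stop("'groups' does not match dim(W)")
  res <- with_seed(seed,
    sim_binary_net(W@p, W@i, W@x, nrow(W), eta, as.integer(steps),
                   as.integer(burn_in), grp, keep_states))
  ng <- nrow(res$group_sums)
  gm <- res$group_sums / as.numeric(gs[seq_len(ng)])
  rownames(gm) <- GROUPS[seq_len(ng)]
  out <- list(group_means = gm,
              population_mean = colSums(res$group_sums) / sum(gs),
              group_sizes = gs, eta = eta, steps = as.integer(steps),
              burn_in = as.integer(burn_in))
  if (keep_states) out$states <- res$states
  structure(out, class = "model_run")
}

#' Build and simulate a network configuration
#'
#' @param config a [network_config()].
#' @param steps,burn_in see [simulate_network()].
#' @param keep_states see [simulate_network()].
#' @param seed optional RNG seed covering both the wiring draw and the
#'   dynamics.
#' @return A `model_run` (the realized connectivity is attached as
#'   attribute `W`).
#' @export
run_model <- function(config, steps, burn_in = 1000, keep_states = FALSE,
                      seed = NULL) {
  with_seed(seed, {
    W <- build_connectivity(config)
    run <- simulate_network(W, config$eta, steps, burn_in, config,
                            keep_states = keep_states)
    attr(run, "W") <- W
    run
  })
}

# winner flips per 1e4 steps: sign changes of the e+ - e- difference with a
# hysteresis dead band (half an SD), so jitter around a locked-in winner or
# a quiescent tie does not count as switching
switching_rate <- function(eplus, eminus) {
  d <- eplus - eminus
  band <- 0.5 * sd(d)
  if (!is.finite(band) || band == 0) return(0)
  s <- sign(d)[abs(d) > band]
  if (length(s) < 2) return(0)
  sum(diff(s) != 0) / length(d) * 1e4
}

#' Event statistics and group correlations of a model run
#'
#' Extracts median-threshold events from each requested group-mean series
#' and from the all-neuron population mean, fits each size distribution
#' with [fit_power_law_range()], and computes the Pearson correlations of
#' the (e+, e-) and (i+, i-) group means. These are the quantities the
#' experimental analysis measures, so a run can be classified against the
#' experimental signature with [classify_match()].
#'
#' @param run a `model_run`.
#' @param fit_groups group names whose event sizes are fit (default the two
#'   excitatory groups; fitting is the expensive step).
#' @param F_criterion,n_surrogate,gap_frac see [fit_power_law_range()].
#' @param seed optional RNG seed for the fitting surrogates.
#' @return List with `fits` (named list of `power_law_fit`), `fit_total`,
#'   `r_eplus`, `r_eminus`, `r_total` (ranges in decades), `corr_e`,
#'   `corr_i`, `switching` (median crossings of the e+ mean per 1e4 steps),
#'   `events` (named list of `event_set`), `events_total`.
#' @export
analyze_run <- function(run, fit_groups = c("e+", "e-"), F_criterion = 0.80,
                        n_surrogate = 500, gap_frac = 0.03, seed = NULL) {
  gm <- run$group_means
  with_seed(seed, {
    fit_series <- function(x) {
      ev <- extract_events(x)
      fit <- if (nrow(ev) >= 3)
        fit_power_law_range(ev$size, F_criterion = F_criterion,
                            n_surrogate = n_surrogate, gap_frac = gap_frac)
      else fit_power_law_range(c(1, 1, 1))
      list(ev = ev, fit = fit)
    }
    fits <- lapply(fit_groups, function(g) fit_series(gm[g, ]))
    names(fits) <- fit_groups
    total <- fit_series(run$population_mean)
    rng <- function(g) if (g %in% fit_groups) fits[[g]]$fit$range_decades
                       else NA_real_
    list(fits = lapply(fits, `[[`, "fit"),
         fit_total = total$fit,
         r_eplus = rng("e+"), r_eminus = rng("e-"),
         r_total = total$fit$range_decades,
         corr_e = cor(gm["e+", ], gm["e-", ]),
         corr_i = cor(gm["i+", ], gm["i-", ]),
         switching = switching_rate(gm["e+", ], gm["e-", ]),
         events = lapply(fits, `[[`, "ev"),
         events_total = total$ev)
  })
}
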