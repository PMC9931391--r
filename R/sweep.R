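#' Scaling exponents across a (drive, eigenvalue) parameter sweep
#'
#' Simulates the model over a grid of external drives and target largest
#' eigenvalues, fits the e+ group-mean event-size distribution at each
#' point, and, for points whose power-law range exceeds `keep_r` decades,
#' measures all three scaling exponents: tau (sizes), alpha (durations of
#' the in-range events) and beta (log-log size-versus-duration slope).
#' A fresh wiring is drawn at every grid point, so the kept-point ensemble
#' averages over graph realizations as well as dynamics; the finite-size
#' critical boundary shifts slightly between realizations, and tying all
#' points to one wiring would correlate their keep/drop decisions.
#'
#' @param etas external drive values.
#' @param Lambdas target largest eigenvalues.
#' @param config base [network_config()]; its `eta` and `Lambda` are
#'   overridden by the grid.
#' @param steps,burn_in simulation length per grid point.
#' @param keep_r minimum power-law range (decades) for a point to enter the
#'   exponent ensemble (default 3).
#' @param F_criterion,n_surrogate fitting parameters.
#' @param seed optional RNG seed covering wiring, dynamics and fitting.
#' @return Data frame with one row per grid point: `eta`, `Lambda`, `r`,
#'   `tau`, `alpha`, `beta` (`NA` for points below `keep_r`), and `kept`.
#' @export
sweep_model_exponents <- function(etas, Lambdas, config = network_config(),
                                  steps = 1e5, burn_in = 1000, keep_r = 3,
                                  F_criterion = 0.80, n_surrogate = 500,
                                  seed = NULL) {
  with_seed(seed, {
    base <- network_config(group_sizes = config$group_sizes,
                           density = config$density, Lambda = 1,
                           eta = config$eta, excitatory = config$excitatory)
    grid <- expand.grid(eta = etas, Lambda = Lambdas)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      eta <- grid$eta[i]; La <- grid$Lambda[i]
      W1 <- build_connectivity(base)
      run <- simulate_network(W1 * La, eta, steps, burn_in, base)
      ev <- extract_events(run$group_means["e+", ])
      out <- data.frame(eta = eta, Lambda = La, r = 0, tau = NA_real_,
                        alpha = NA_real_, beta = NA_real_, kept = FALSE)
      if (nrow(ev) < 30) return(out)
      fit <- fit_power_law_range(ev$size, F_criterion = F_criterion,
                                 n_surrogate = n_surrogate)
      out$r <- fit$range_decades
      if (fit$range_decades > keep_r) {
        out$tau <- fit$tau
        out$alpha <- duration_exponent(ev, fit,
                                       n_surrogate = n_surrogate)$alpha
        out$beta <- size_vs_duration(ev, fit)$beta
        out$kept <- TRUE
      }
      out
    })
    do.call(rbind, rows)
  })
}
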