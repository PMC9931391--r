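# lazily computed, cached canonical model run shared by the acceptance
# tests (several criteria are measured on the same long simulation)
.canonical_cache <- new.env(parent = emptyenv())

canonical_analysis <- function() {
  if (is.null(.canonical_cache$an)) {
    run <- run_model(network_config(), steps = 1e5, burn_in = 1000,
                     seed = 101)
    .canonical_cache$an <- analyze_run(run, fit_groups = c("e+", "e-"),
                                       n_surrogate = 500, seed = 102)
  }
  .canonical_cache$an
}

# small planted population reused across subset/null tests
.planted_cache <- new.env(parent = emptyenv())

planted_fixture <- function() {
  if (is.null(.planted_cache$pp)) {
    .planted_cache$pp <- make_planted_population(
      n_neurons = 300, group_sizes = c(groupA = 60, groupB = 60),
      t_samples = 10000, dt = 1 / 3, seed = 77)
  }
  .planted_cache$pp
}

# the subset pipeline operates on conditioned traces (z-score + low-pass)
planted_preprocessed <- function() {
  if (is.null(.planted_cache$act)) {
    .planted_cache$act <- preprocess_activity(planted_fixture()$activity,
                                              dt = 1 / 3)
  }
  .planted_cache$act
}
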