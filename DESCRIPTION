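Package: crackling
Title: Scale-Free Event Statistics and Winner-Take-All Network Models for
    Neural and Behavioral Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying scale-free dynamics in continuous neural
    and behavioral time series. Defines events as suprathreshold excursions
    of a series above its median, measures event sizes (threshold-integrated
    areas) and durations, and estimates the range of sizes consistent with a
    truncated power law by maximum likelihood with a surrogate-data
    goodness-of-fit test. Includes duration and size-versus-duration scaling
    exponents with the crackling-noise prediction, seed-based discovery of
    correlated neuron subsets with cyclic time-shift null controls,
    event-specific behavior-neural correlation statistics, a four-population
    probabilistic binary-neuron model with eigenvalue-normalized block
    connectivity exhibiting stochastic winner-take-all switching, a
    combinatorial search over block-connectivity configurations, and
    synthetic-data generators with planted scale-free structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    Matrix,
    methods,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    data.table,
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
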