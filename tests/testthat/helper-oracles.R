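# independent reference implementations used to cross-check the package

# per-sample scan event extraction (no rle); rectangle rule
naive_extract_events <- function(v, thr, dt = 1) {
  sizes <- durations <- numeric(0)
  cur_size <- 0; cur_len <- 0
  for (x in c(v, -Inf)) {  # sentinel flushes a trailing event
    if (is.finite(x) && x > thr) {
      cur_size <- cur_size + (x - thr) * dt
      cur_len <- cur_len + 1
    } else if (cur_len > 0) {
      if (cur_size > 0) {
        sizes <- c(sizes, cur_size)
        durations <- c(durations, cur_len * dt)
      }
      cur_size <- 0; cur_len <- 0
    }
  }
  list(size = sizes, duration = durations)
}

# truncated power-law log-likelihood with numerically integrated
# normalization (independent of the closed-form constant in the package)
numint_loglik <- function(s, tau, s_min, s_max) {
  C <- 1 / stats::integrate(function(x) x^(-tau), s_min, s_max,
                            rel.tol = 1e-12)$value
  sum(log(C) - tau * log(s))
}

# admissibility via igraph weak connectivity
oracle_admissible <- function(D) {
  if (D[1, 1] == 0 || D[2, 2] == 0) return(FALSE)
  if (all(D[3:4, 1:2] == 0)) return(FALSE)
  if (all(D[1:2, 3:4] == 0)) return(FALSE)
  A <- (D > 0) * 1
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  igraph::is_connected(g, mode = "weak")
}

random_density <- function() matrix(sample(c(0, 0.05, 0.5), 16, replace = TRUE), 4, 4)
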