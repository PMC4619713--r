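# Independent oracles used across the suite. These deliberately use different
# computational routes from the package internals they check.

# Kolmogorov survival function via the plain alternating series
# Q(l) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 l^2)
# (the package uses the Jacobi-theta dual form).
oracle_kolmogorov_q <- function(lambda) {
  if (lambda <= 1e-8) return(1)
  k <- 1:500
  q <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(q, 0), 1)
}

# Brute-force two-sample KS on a pair of curves under the package's stated
# normalization convention (joint-minimum shift, unit mass, cumulative over
# angle), with the oracle p-value above.
oracle_ks_phard <- function(int1, int2) {
  shift <- min(c(int1, int2))
  w1 <- int1 - shift; w2 <- int2 - shift
  F1 <- cumsum(w1) / sum(w1)
  F2 <- cumsum(w2) / sum(w2)
  D <- 0
  for (i in seq_along(F1)) D <- max(D, abs(F1[i] - F2[i]))
  nb <- length(int1)
  list(D = D, p = oracle_kolmogorov_q(sqrt(nb / 2) * D))
}

# Exhaustive optimal open-path length from a fixed start (for small n).
oracle_best_path <- function(x, y, start) {
  n <- length(x)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    px <- c(start[1], x[p]); py <- c(start[2], y[p])
    len <- sum(sqrt(diff(px)^2 + diff(py)^2))
    if (len < best) best <- len
  }
  best
}

path_length <- function(x, y, start) {
  sum(sqrt(diff(c(start[1], x))^2 + diff(c(start[2], y))^2))
}

# small seascape configuration used where full-size grids are unnecessary
small_config <- function(seed = 1, ...) {
  seascape_config(grid_nx = 80, grid_ny = 80, cell_size = 25,
                  field_smoothness = 6, seed = seed, ...)
}

# memoized heavy simulation shared by the acceptance tests
.accept_cache <- new.env(parent = emptyenv())
acceptance_coverage_sim <- function() {
  if (is.null(.accept_cache$cs)) {
    .accept_cache$cs <- coverage_simulation(seascape_config(seed = 101),
                                            n_sites = 40, n_rep = 1000,
                                            seed = 1)
  }
  .accept_cache$cs
}
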