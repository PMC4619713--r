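#' Replicate-draw validation of design-based estimates
#'
#' Monte-Carlo check of the whole design-based chain on a seascape with known
#' ground truth: a fixed synthetic seascape is generated, and for each
#' replicate a fresh GRTS sample of `n_sites` candidate sites is drawn,
#' per-site class proportions are read off the true class raster, and Hajek
#' ratio estimates with local-neighborhood-variance 95% intervals are formed.
#' Reports, per substrate class, the empirical coverage of the nominal 95%
#' intervals, the mean estimate, and the known truth — the standard way to
#' verify that a design-based estimator is unbiased and its intervals hold
#' their nominal level.
#'
#' @param config a [seascape_config()]; defines the fixed seascape.
#' @param n_sites sites per replicate draw (default 40).
#' @param n_rep number of replicate draws (default 1000).
#' @param seed integer root seed for the replicate draws.
#' @param site_edge_m candidate-site edge length (default 200 m).
#' @return A `coverage_simulation` list: `coverage_pct`, `mean_estimate`,
#'   `truth_pct` (each a named length-3 vector), `n_rep`, `n_sites`, and
#'   `estimates` (the `n_rep` x 3 matrix of replicate estimates).
#' @export
coverage_simulation <- function(config = seascape_config(), n_sites = 40L,
                                n_rep = 1000L, seed = 1L,
                                site_edge_m = 200) {
  truth <- generate_seascape(config)
  frame <- site_frame(truth, site_edge_m)
  props <- frame_class_proportions(truth$class, frame)
  truth_pct <- 100 * colMeans(props)
  est <- matrix(NA_real_, n_rep, 3)
  covered <- matrix(NA, n_rep, 3)
  for (r in seq_len(n_rep)) {
    m <- grts_master(frame, n_sites, seed = derive_seed(seed, 100L + r))
    idx <- match(m$unit_id, frame$unit_id)
    s <- data.frame(x = m$x, y = m$y, pi = m$pi,
                    prop_hard = props[idx, 1], prop_mixed = props[idx, 2],
                    prop_soft = props[idx, 3])
    e <- ht_category_estimate(s)
    est[r, ] <- e$estimate
    covered[r, ] <- e$lcb95 <= truth_pct & truth_pct <= e$ucb95
  }
  cls <- c("hard", "mixed", "soft")
  structure(list(coverage_pct = stats::setNames(100 * colMeans(covered), cls),
                 mean_estimate = stats::setNames(colMeans(est), cls),
                 truth_pct = stats::setNames(as.vector(truth_pct), cls),
                 n_rep = n_rep, n_sites = n_sites, estimates = est),
            class = "coverage_simulation")
}

#' @export
print.coverage_simulation <- function(x, ...) {
  cat("Replicate-draw validation:", x$n_rep, "GRTS draws of", x$n_sites,
      "sites\n")
  for (k in names(x$coverage_pct)) {
    cat(sprintf("  %-6s truth %5.2f%%  mean estimate %5.2f%%  95%% CI coverage %4.1f%%\n",
                k, x$truth_pct[k], x$mean_estimate[k], x$coverage_pct[k]))
  }
  invisible(x)
}
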