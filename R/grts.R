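#' Build a finite sampling frame
#'
#' A sampling frame is the finite population of candidate sites (cells or
#' points) from which spatially balanced samples are drawn. Inclusion
#' intensities `pi` are relative: they are rescaled at draw time so they sum
#' to the requested sample size (with the standard certainty-unit
#' re-normalization when any rescaled probability exceeds 1).
#'
#' @param x,y site coordinates in metres (plane coordinates).
#' @param pi optional relative inclusion intensities (> 0); equal by default.
#' @param unit_id optional unique identifiers; defaults to `1:n`.
#' @param class optional auxiliary class label per unit (used e.g. for
#'   class-weighted phase-II designs).
#' @return A `sampling_frame`: a data.frame with columns `unit_id`, `x`, `y`,
#'   `pi` (and `class` if given) and an `extent` attribute
#'   `c(xmin, xmax, ymin, ymax)`.
#' @export
sampling_frame <- function(x, y, pi = NULL, unit_id = NULL, class = NULL) {
  n <- length(x)
  if (length(y) != n || n < 1) stop("x and y must have equal positive length",
                                    call. = FALSE)
  if (is.null(pi)) pi <- rep(1, n)
  if (any(!is.finite(pi)) || any(pi <= 0))
    stop("all inclusion intensities must be positive and finite", call. = FALSE)
  if (is.null(unit_id)) unit_id <- seq_len(n)
  if (anyDuplicated(unit_id)) stop("unit_id values must be unique", call. = FALSE)
  fr <- data.frame(unit_id = unit_id, x = x, y = y, pi = pi)
  if (!is.null(class)) fr$class <- class
  ext <- c(xmin = min(x), xmax = max(x), ymin = min(y), ymax = max(y))
  if (ext[2] - ext[1] <= 0 && ext[4] - ext[3] <= 0 && n > 1)
    stop("frame extent has zero area (all units co-located)", call. = FALSE)
  attr(fr, "extent") <- ext
  class(fr) <- c("sampling_frame", "data.frame")
  fr
}

# Rescale relative intensities so they sum to n, iterating the certainty-unit
# loop: any probability that would exceed 1 is fixed at 1 and the remainder
# re-normalized over the rest.
normalize_pi <- function(pi, n) {
  if (n > length(pi)) stop("sample size exceeds population size", call. = FALSE)
  p <- rep(NA_real_, length(pi))
  certain <- rep(FALSE, length(pi))
  repeat {
    rem <- n - sum(certain)
    free <- !certain
    scaled <- pi[free] / sum(pi[free]) * rem
    if (all(scaled <= 1 + 1e-12)) {
      p[free] <- pmin(scaled, 1)
      p[certain] <- 1
      break
    }
    newly <- free
    newly[free] <- scaled >= 1
    certain <- certain | newly
    if (all(certain)) { p[] <- 1; break }
  }
  p
}

# Reverse hierarchical order of ranks 0..(n-1): write each rank in binary,
# reverse the digits, and order by the reversed (van der Corput) value. Every
# prefix of the resulting permutation is a low-discrepancy subset of the
# randomized address line — repeatedly bisecting it — hence spatially
# balanced, for prefixes of any length (base 2 avoids the pairing artefacts
# coarser radixes show at prefix sizes between radix powers).
reverse_hierarchical_order <- function(n) {
  if (n <= 1) return(seq_len(n))
  nd <- max(1L, ceiling(log2(n) - 1e-12))
  r <- 0:(n - 1)
  rev_val <- numeric(n)
  v <- r
  for (d in seq_len(nd)) {
    rev_val <- rev_val * 2 + (v %% 2)
    v <- v %/% 2
  }
  order(rev_val, r)
}

# Hierarchically randomized order of frame units: recursive quadrant
# addressing of the (squared) extent with an independent uniform key for every
# node/child, so sorting by the key sequence applies an independent random
# permutation of the four sub-quadrants at every node.
hierarchical_order <- function(x, y, extent, max_depth = 14L) {
  n <- length(x)
  side <- max(extent["xmax"] - extent["xmin"], extent["ymax"] - extent["ymin"])
  if (side <= 0) stop("frame extent has zero area", call. = FALSE)
  # co-located units: seeded jitter of 1e-6 * extent breaks address ties
  dup <- duplicated(cbind(x, y))
  if (any(dup)) {
    x[dup] <- x[dup] + stats::runif(sum(dup), -1e-6, 1e-6) * side
    y[dup] <- y[dup] + stats::runif(sum(dup), -1e-6, 1e-6) * side
  }
  u <- (x - extent["xmin"]) / side
  v <- (y - extent["ymin"]) / side
  u <- pmin(pmax(u, 0), 1 - 1e-12)
  v <- pmin(pmax(v, 0), 1 - 1e-12)
  K <- min(max_depth, max(4L, as.integer(ceiling(log(max(n, 4)) / log(4))) + 2L))
  keys <- vector("list", K)
  node <- rep(0, n)  # base-4 address of the enclosing cell, as a number
  for (l in seq_len(K)) {
    cx <- floor(u * 2^l); cy <- floor(v * 2^l)
    digit <- (cy %% 2) * 2 + (cx %% 2)
    idx <- node * 4 + digit           # cell id at level l in 0..4^l-1
    r <- stats::runif(4^l)            # one key per (node, child)
    keys[[l]] <- r[idx + 1]
    node <- idx
  }
  keys[[K + 1L]] <- stats::runif(n)   # final tie-break
  do.call(order, keys)
}

#' Draw a GRTS master sample
#'
#' Draws a spatially balanced sample by Generalized Random Tessellation
#' Stratified (GRTS) sampling: the frame extent is recursively partitioned
#' into quadrants with an independent random permutation of the four
#' sub-quadrants at every node, mapping units onto a randomized base-4
#' address line; units occupy segments of length proportional to their
#' (normalized) inclusion probability and a systematic sample with a random
#' start selects `n_master` of them, giving exact first-order inclusion
#' probabilities. The selected sites are then re-ordered by reverse
#' hierarchical ordering so that *any prefix* of the master sample is itself
#' a spatially balanced sample — this is what makes an "overly large" master
#' sample useful: field effort can stop (or resume) at any point in the
#' ordering without sacrificing design validity.
#'
#' @param frame a [sampling_frame()].
#' @param n_master number of sites to draw (at most the frame size).
#' @param seed integer seed; the same frame and seed give an identical draw.
#' @return A `grts_master` object: a data.frame of the selected sites with
#'   columns `unit_id`, `x`, `y`, `pi` (the realized inclusion probability)
#'   and `order_index` (0-based reverse-hierarchical position), sorted by
#'   `order_index`, plus attributes `seed`, `n_master` and `frame`.
#' @seealso [prefix_subset()], [spatial_balance()], [adjust_inclusion()]
#' @examples
#' fr <- sampling_frame(runif(500, 0, 1000), runif(500, 0, 1000))
#' ms <- grts_master(fr, 100, seed = 42)
#' head(prefix_subset(ms, 30))
#' @export
grts_master <- function(frame, n_master, seed) {
  stopifnot(inherits(frame, "sampling_frame"))
  n_master <- as.integer(n_master)
  if (n_master < 1L) stop("n_master must be at least 1", call. = FALSE)
  if (n_master > nrow(frame))
    stop("n_master exceeds the number of frame units", call. = FALSE)
  set.seed(as.integer(seed))
  p <- normalize_pi(frame$pi, n_master)
  ord <- hierarchical_order(frame$x, frame$y, attr(frame, "extent"))
  p_line <- p[ord]
  cum <- cumsum(p_line)
  start <- stats::runif(1)
  pts <- start + 0:(n_master - 1)
  sel_line <- findInterval(pts, cum) + 1L   # p_i <= 1 => at most one hit/unit
  sel_line <- pmin(sel_line, length(ord))
  sel <- ord[sel_line]                      # selected, in line order
  rho <- reverse_hierarchical_order(n_master)
  sel <- sel[rho]
  out <- data.frame(unit_id = frame$unit_id[sel],
                    x = frame$x[sel], y = frame$y[sel],
                    pi = p[sel],
                    order_index = 0:(n_master - 1))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_master") <- n_master
  attr(out, "frame") <- frame
  class(out) <- c("grts_master", "data.frame")
  out
}

#' Take the first n sites of a master sample
#'
#' Prefixes of a reverse-hierarchically ordered master sample are themselves
#' spatially balanced samples, so survey effort can scale in increments
#' (e.g. 30, 35, ..., 100 sites) while retaining a statistically valid design.
#' Prefixes nest: `prefix_subset(m, a)` is contained in `prefix_subset(m, b)`
#' whenever `a <= b`.
#'
#' @param master a [grts_master()] object.
#' @param n prefix length, at most `n_master`.
#' @return The first `n` rows (by `order_index`).
#' @export
prefix_subset <- function(master, n) {
  stopifnot(inherits(master, "grts_master"))
  if (n > attr(master, "n_master"))
    stop("prefix length exceeds the master sample size", call. = FALSE)
  if (n < 1) stop("prefix length must be at least 1", call. = FALSE)
  master[master$order_index < n, , drop = FALSE]
}

#' One-dimensional GRTS: balanced points along a line
#'
#' Selects `n` positions on a transect of length `line_length` by the
#' one-dimensional analogue of GRTS, with the recursive binary segmentation
#' carried to its maximal depth of one selection per terminal segment: the
#' line is divided into `n` equal segments, each contributes one uniformly
#' jittered position (so every segment's inclusion is certain and the sample
#' is maximally stratified along the line — consecutive sorted positions are
#' never more than two segment widths apart), and the positions are returned
#' in reverse hierarchical (bit-reversed) segment order so any prefix is
#' itself balanced along the line. Used, e.g., to pick a balanced subset of
#' images along a camera transect.
#'
#' @param line_length transect length in metres (> 0).
#' @param n number of points (>= 1).
#' @param seed integer seed.
#' @return Numeric vector of `n` positions in `[0, line_length)`, in reverse
#'   hierarchical order.
#' @export
draw_points_on_line <- function(line_length, n, seed) {
  if (line_length <= 0) stop("line_length must be positive", call. = FALSE)
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  set.seed(as.integer(seed))
  pos <- (0:(n - 1) + stats::runif(n)) * (line_length / n)
  pos[reverse_hierarchical_order(n)]
}

#' Adjust inclusion probabilities for realized sample size
#'
#' When fewer (or more) sites are visited than planned, design-based
#' estimation stays valid if the first-order inclusion probabilities are
#' scaled by the realized fraction: `pi * n_realized / n_planned`, clamped
#' to (0, 1].
#'
#' @param pi_design design inclusion probability/probabilities in (0, 1].
#' @param n_planned planned number of sites (> 0).
#' @param n_realized number actually visited (> 0).
#' @return Adjusted probabilities, same length as `pi_design`.
#' @export
adjust_inclusion <- function(pi_design, n_planned, n_realized) {
  if (n_planned <= 0) stop("n_planned must be positive", call. = FALSE)
  if (n_realized <= 0) stop("n_realized must be positive", call. = FALSE)
  if (any(pi_design <= 0) || any(pi_design > 1))
    stop("pi_design must lie in (0, 1]", call. = FALSE)
  pmin(pi_design * n_realized / n_planned, 1)
}

#' Voronoi-based spatial balance of a site set
#'
#' Measures how evenly a set of selected sites covers the frame: every frame
#' unit is assigned to its nearest site (the site's Voronoi cell in the
#' finite frame) and the total (normalized) inclusion probability landing in
#' each cell is computed. For a perfectly balanced sample each cell captures
#' probability 1; the balance loss is the variance of these cell totals.
#' Lower is better. A simple-random-sampling reference value is estimated by
#' internal replication so GRTS draws can be judged against SRS.
#'
#' @param sites data.frame with columns `x`, `y` (e.g. a master-sample
#'   prefix). Duplicate coordinates are an error.
#' @param frame the [sampling_frame()] the sites were drawn from.
#' @param n_ref number of SRS replicate draws for the reference value.
#' @param ref_seed seed for the internal SRS replication.
#' @return A `balance_report` list: `metric_value`, `n_sites`,
#'   `reference_value`.
#' @export
spatial_balance <- function(sites, frame, n_ref = 100L, ref_seed = 1L) {
  stopifnot(inherits(frame, "sampling_frame"))
  if (nrow(sites) < 2) stop("need at least 2 sites", call. = FALSE)
  if (anyDuplicated(sites[, c("x", "y")]))
    stop("duplicate site coordinates; jitter co-located sites before calling",
         call. = FALSE)
  ext <- attr(frame, "extent")
  if (any(sites$x < ext["xmin"] - 1e-9) || any(sites$x > ext["xmax"] + 1e-9) ||
      any(sites$y < ext["ymin"] - 1e-9) || any(sites$y > ext["ymax"] + 1e-9))
    stop("sites outside the frame extent", call. = FALSE)
  loss <- balance_loss(sites$x, sites$y, frame)
  n <- nrow(sites)
  set.seed(as.integer(ref_seed))
  ref <- mean(vapply(seq_len(n_ref), function(i) {
    idx <- sample.int(nrow(frame), n)
    balance_loss(frame$x[idx], frame$y[idx], frame)
  }, numeric(1)))
  structure(list(metric_value = loss, n_sites = n, reference_value = ref),
            class = "balance_report")
}

# variance of per-site captured inclusion probability (normalized to n sites)
balance_loss <- function(sx, sy, frame) {
  n <- length(sx)
  p <- frame$pi / sum(frame$pi) * n
  nearest <- nearest_site(frame$x, frame$y, sx, sy)
  v <- vapply(seq_len(n), function(j) sum(p[nearest == j]), numeric(1))
  mean((v - mean(v))^2)
}

# index of nearest site for every unit; chunked to bound memory
nearest_site <- function(ux, uy, sx, sy, chunk = 20000L) {
  out <- integer(length(ux))
  for (s in seq(1L, length(ux), by = chunk)) {
    e <- min(s + chunk - 1L, length(ux))
    d2 <- outer(ux[s:e], sx, "-")^2 + outer(uy[s:e], sy, "-")^2
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' @export
print.grts_master <- function(x, ...) {
  cat("GRTS master sample:", attr(x, "n_master"), "sites (seed",
      attr(x, "seed"), ")\n")
  cat("Any prefix (by order_index) is itself spatially balanced.\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more sites\n")
  invisible(x)
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("Spatial balance over %d sites: loss %.4f (SRS reference %.4f)\n",
              x$n_sites, x$metric_value, x$reference_value))
  invisible(x)
}

#' @export
plot.grts_master <- function(x, n = NULL, ...) {
  fr <- attr(x, "frame")
  graphics::plot(fr$x, fr$y, pch = ".", col = "grey70",
                 xlab = "x (m)", ylab = "y (m)", asp = 1, ...)
  s <- if (is.null(n)) x else prefix_subset(x, n)
  graphics::points(s$x, s$y, pch = 19, col = "firebrick")
  invisible(x)
}
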