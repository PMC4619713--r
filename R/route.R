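#' Efficient visiting routes for nested site subsets
#'
#' For each requested sample-size increment, computes a short open route from
#' a fixed start point (e.g. the anchorage) through the corresponding
#' master-sample prefix. Routes are built by nearest-neighbour construction
#' followed by 2-opt segment reversals alternated with single-site relocation
#' on Euclidean plane distances; the route for each increment is computed
#' independently (the site *sets* nest, the routes need not).
#'
#' @param master a [grts_master()] object.
#' @param increments ascending vector of prefix sizes, max at most `n_master`.
#' @param start_point numeric `c(x, y)` start coordinates in metres.
#' @return A data.frame with one row per visited site per increment:
#'   `increment`, `leg_order` (1 = first site after the start), `unit_id`,
#'   `cumulative_km`. Attribute `"lengths_km"` gives total length per
#'   increment.
#' @examples
#' fr <- sampling_frame(runif(200, 0, 5000), runif(200, 0, 5000))
#' ms <- grts_master(fr, 100, seed = 3)
#' r <- nested_routes(ms, seq(30, 100, by = 5), start_point = c(0, 0))
#' attr(r, "lengths_km")
#' @export
nested_routes <- function(master, increments, start_point) {
  stopifnot(inherits(master, "grts_master"))
  if (length(increments) == 0) stop("increments must be non-empty", call. = FALSE)
  if (is.unsorted(increments)) stop("increments must be ascending", call. = FALSE)
  if (max(increments) > attr(master, "n_master"))
    stop("largest increment exceeds the master sample size", call. = FALSE)
  out <- vector("list", length(increments))
  lens <- numeric(length(increments))
  for (k in seq_along(increments)) {
    n <- increments[k]
    s <- prefix_subset(master, n)
    ordr <- route_order(s$x, s$y, start_point, s$unit_id)
    xs <- s$x[ordr]; ys <- s$y[ordr]
    legs <- sqrt(diff(c(start_point[1], xs))^2 + diff(c(start_point[2], ys))^2)
    cum_km <- cumsum(legs) / 1000
    lens[k] <- cum_km[length(cum_km)]
    out[[k]] <- data.frame(increment = n, leg_order = seq_len(n),
                           unit_id = s$unit_id[ordr], cumulative_km = cum_km)
  }
  res <- do.call(rbind, out)
  attr(res, "lengths_km") <- stats::setNames(lens, increments)
  res
}

# Open-path heuristic: nearest-neighbour construction (ties broken by lowest
# unit_id) improved by 2-opt + relocation, restarted deterministically from
# several forced first sites to escape construction-order local optima; the
# shortest improved path wins (ties by construction order).
route_order <- function(x, y, start_point, unit_id = seq_along(x)) {
  n <- length(x)
  if (n == 1L) return(1L)
  nn_from <- function(first) {
    visited <- logical(n)
    ordr <- integer(n)
    cx <- start_point[1]; cy <- start_point[2]
    for (k in seq_len(n)) {
      if (k == 1L && !is.na(first)) {
        nxt <- first
      } else {
        d <- (x - cx)^2 + (y - cy)^2
        d[visited] <- Inf
        cand <- which(d == min(d))
        nxt <- cand[which.min(unit_id[cand])]
      }
      ordr[k] <- nxt
      visited[nxt] <- TRUE
      cx <- x[nxt]; cy <- y[nxt]
    }
    ordr
  }
  plen <- function(o) sum(sqrt(diff(c(start_point[1], x[o]))^2 +
                                 diff(c(start_point[2], y[o]))^2))
  firsts <- c(NA_integer_, order(unit_id)[seq_len(min(n, 8L))])
  best <- NULL; best_len <- Inf
  for (f in firsts) {
    o <- improve_path(nn_from(f), x, y, start_point)
    l <- plen(o)
    if (l < best_len - 1e-12) { best <- o; best_len <- l }
  }
  best
}

# alternate 2-opt reversals with single-node relocation (or-opt) until
# neither finds an improvement; relocation rescues the local optima plain
# 2-opt hits on open paths
improve_path <- function(ordr, x, y, start_point, max_round = 25L) {
  for (round in seq_len(max_round)) {
    before <- ordr
    ordr <- two_opt(ordr, x, y, start_point)
    ordr <- or_opt(ordr, x, y, start_point)
    if (identical(ordr, before)) break
  }
  ordr
}

# 2-opt for an open path with a fixed start node. Site position k sits at
# path index k + 1 (index 1 is the start). Reversing sites a..b replaces
# edges (a-1 -> a) and (b -> b+1); the last site has no outgoing edge.
two_opt <- function(ordr, x, y, start_point, max_pass = 50L) {
  n <- length(ordr)
  if (n < 2L) return(ordr)
  px <- c(start_point[1], x[ordr])
  py <- c(start_point[2], y[ordr])
  d <- function(i, j) sqrt((px[i] - px[j])^2 + (py[i] - py[j])^2)
  improved <- TRUE; pass <- 0L
  while (improved && pass < max_pass) {
    improved <- FALSE; pass <- pass + 1L
    for (a in 1:(n - 1L)) {
      for (b in (a + 1L):n) {
        old <- d(a, a + 1L) + if (b < n) d(b + 1L, b + 2L) else 0
        new <- d(a, b + 1L) + if (b < n) d(a + 1L, b + 2L) else 0
        if (new + 1e-12 < old) {
          seg <- (a + 1L):(b + 1L)
          px[seg] <- px[rev(seg)]; py[seg] <- py[rev(seg)]
          ordr[a:b] <- ordr[b:a]
          improved <- TRUE
        }
      }
    }
  }
  ordr
}

# Relocate single sites to better positions (first-improvement passes).
# Path indices: start = 1, site k = k + 1; the last site has no outgoing edge.
or_opt <- function(ordr, x, y, start_point, max_pass = 50L) {
  n <- length(ordr)
  if (n < 3L) return(ordr)
  improved <- TRUE; pass <- 0L
  while (improved && pass < max_pass) {
    improved <- FALSE; pass <- pass + 1L
    px <- c(start_point[1], x[ordr])
    py <- c(start_point[2], y[ordr])
    d <- function(i, j) sqrt((px[i] - px[j])^2 + (py[i] - py[j])^2)
    for (a in 1:n) {          # site position to move
      ia <- a + 1L
      rem <- d(ia - 1L, ia) + if (a < n) d(ia, ia + 1L) else 0
      rejoin <- if (a < n) d(ia - 1L, ia + 1L) else 0
      gain0 <- rem - rejoin
      for (b in 0:n) {        # insert after site position b (0 = after start)
        if (b == a || b == a - 1L) next
        ib <- b + 1L
        add <- d(ib, ia) + if (b < n) d(ia, ib + 1L) else 0
        cut <- if (b < n) d(ib, ib + 1L) else 0
        if (add - cut + 1e-12 < gain0) {
          site <- ordr[a]
          rest <- ordr[-a]
          pos <- if (b < a) b else b - 1L
          ordr <- append(rest, site, after = pos)
          improved <- TRUE
          px <- c(start_point[1], x[ordr])
          py <- c(start_point[2], y[ordr])
          break
        }
      }
      if (improved) break
    }
  }
  ordr
}
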