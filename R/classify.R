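#' Construct an angular response curve
#'
#' @param angles incidence angles in degrees, strictly increasing, >= 5 bins.
#' @param intensities backscatter in dB, one per angle.
#' @param cell_id optional identifier.
#' @return An `arc_curve` object.
#' @export
arc_curve <- function(angles, intensities, cell_id = NA) {
  if (length(angles) != length(intensities))
    stop("angles and intensities must have equal length", call. = FALSE)
  if (length(angles) < 5) stop("need at least 5 angle bins", call. = FALSE)
  if (any(diff(angles) <= 0)) stop("angles must be strictly increasing",
                                   call. = FALSE)
  structure(list(angles = angles, intensities = intensities, cell_id = cell_id),
            class = "arc_curve")
}

#' Average training curves into a hard-seabed reference ARC
#'
#' The reference curve is the pointwise mean backscatter of training curves
#' taken over seabed known (from imagery) to be hard. Every other curve in a
#' survey is later compared against this reference to score its probability
#' of hardness.
#'
#' @param training list of [arc_curve()] objects (>= 2) on a common angle grid.
#' @return A `reference_arc`: an [arc_curve()] with `n_training` recorded.
#' @export
build_reference_arc <- function(training) {
  if (length(training) < 2)
    stop("need at least 2 training curves", call. = FALSE)
  a0 <- training[[1]]$angles
  for (cv in training) {
    if (length(cv$angles) != length(a0) || any(cv$angles != a0))
      stop("training curves are not on a common angle grid", call. = FALSE)
  }
  m <- colMeans(do.call(rbind, lapply(training, `[[`, "intensities")))
  ref <- arc_curve(a0, m)
  ref$n_training <- length(training)
  ref$source_class <- "hard"
  class(ref) <- c("reference_arc", "arc_curve")
  ref
}

# Normalize paired curves to unit-mass distributions over angle: shift both
# by their joint minimum so masses are non-negative, then divide by each
# curve's total. This is the one place the ARC-to-distribution convention
# lives; the Kolmogorov-Smirnov comparison consumes its output.
arc_to_cdf_pair <- function(int1, int2) {
  shift <- min(c(int1, int2))
  w1 <- int1 - shift; w2 <- int2 - shift
  s1 <- sum(w1); s2 <- sum(w2)
  if (s1 <= 0 || s2 <= 0)
    stop("flat curve: zero total mass after shifting, p-hard undefined",
         call. = FALSE)
  list(F1 = cumsum(w1) / s1, F2 = cumsum(w2) / s2)
}

#' Probability of hard seabed from a KS comparison to the reference ARC
#'
#' Converts the cell's curve and the hard-seabed reference to cumulative
#' distributions over angle (joint-minimum shift, unit mass) and computes the
#' two-sample Kolmogorov-Smirnov statistic `D = max |F_cell - F_ref|`. The
#' returned `p_hard` is the asymptotic KS p-value at effective size
#' `n_bins / 2`, so curves indistinguishable from the hard reference score
#' near 1 and curves with a very different angular shape score near 0;
#' `p_hard` is monotone non-increasing in `D`.
#'
#' @param curve an [arc_curve()].
#' @param reference a [build_reference_arc()] result on the same angle grid.
#' @return `p_hard` in `[0, 1]`, with attribute `"D"` (the KS statistic).
#' @export
ks_phard <- function(curve, reference) {
  if (length(curve$angles) != length(reference$angles) ||
      any(curve$angles != reference$angles))
    stop("curve and reference must share the angle grid", call. = FALSE)
  cdfs <- arc_to_cdf_pair(curve$intensities, reference$intensities)
  D <- max(abs(cdfs$F1 - cdfs$F2))
  nb <- length(curve$angles)
  p <- kolmogorov_q(sqrt(nb / 2) * D)
  attr(p, "D") <- D
  p
}

#' Vectorized p-hard over an ARC field
#'
#' Applies the [ks_phard()] construction to every row of an ARC field matrix
#' (one curve per cell) against the hard-seabed reference, returning the
#' per-cell probability of hardness.
#'
#' @param arc numeric matrix, cells by angles (as from [simulate_arc_field()]).
#' @param reference a [build_reference_arc()] result on the same angle grid.
#' @return Numeric vector of p-hard values, one per row of `arc`.
#' @export
phard_field <- function(arc, reference) {
  nb <- ncol(arc)
  refI <- reference$intensities
  row_min <- do.call(pmin, as.data.frame(arc))
  shift <- pmin(row_min, min(refI))
  U <- upper.tri(matrix(0, nb, nb), diag = TRUE) + 0  # running-sum operator
  w <- arc - shift
  Fc <- (w %*% U) / rowSums(w)
  wr <- outer(-shift, refI, "+")
  Fr <- (wr %*% U) / rowSums(wr)
  D <- do.call(pmax, as.data.frame(abs(Fc - Fr)))
  kolmogorov_q(sqrt(nb / 2) * D)
}

#' Inverse-distance-weighted interpolation onto a grid
#'
#' Interpolates scattered observations (e.g. site-level p-hard values) onto
#' cell centres with weights `distance^-power` over all observations; a cell
#' coincident with an observation takes that observation's value exactly.
#' Interpolated values are always within the range of the observations.
#'
#' @param obs data.frame with columns `x`, `y`, `value`.
#' @param grid_x,grid_y cell-centre coordinate vectors of the target grid.
#' @param power IDW exponent (default 2).
#' @return List with `values` (matrix, `length(grid_y)` rows by
#'   `length(grid_x)` columns) and `provenance` (matrix, `"observed"` where a
#'   cell coincides with an input point, else `"interpolated"`).
#' @export
idw_interpolate <- function(obs, grid_x, grid_y, power = 2) {
  if (nrow(obs) < 1) stop("need at least one observation", call. = FALSE)
  gx <- rep(grid_x, each = length(grid_y))
  gy <- rep(grid_y, times = length(grid_x))
  d2 <- outer(gx, obs$x, "-")^2 + outer(gy, obs$y, "-")^2
  d <- sqrt(d2)
  hit <- d < 1e-9
  w <- d^(-power)
  w[hit] <- 0                      # exact cells handled separately
  val <- as.vector(w %*% obs$value) / rowSums(w)
  prov <- rep("interpolated", length(gx))
  any_hit <- rowSums(hit) > 0
  if (any(any_hit)) {
    val[any_hit] <- obs$value[apply(hit[any_hit, , drop = FALSE], 1, which.max)]
    prov[any_hit] <- "observed"
  }
  list(values = matrix(val, length(grid_y), length(grid_x)),
       provenance = matrix(prov, length(grid_y), length(grid_x)))
}

#' Classify a p-hard layer into hard / mixed / soft
#'
#' Thresholds the probability-of-hardness layer: `p > hi` is hard,
#' `lo <= p <= hi` is mixed (both endpoints inclusive), `p < lo` is soft.
#' Defaults are the 10% and 90% cut points.
#'
#' @param p numeric vector or matrix of p-hard values in `[0, 1]`.
#' @param lo,hi cut points with `lo < hi`.
#' @return Character vector/matrix of class labels, same shape as `p`.
#' @export
classify_phard <- function(p, lo = 0.10, hi = 0.90) {
  if (lo >= hi) stop("lo must be strictly less than hi", call. = FALSE)
  out <- ifelse(p > hi, "hard", ifelse(p < lo, "soft", "mixed"))
  if (is.matrix(p)) out <- matrix(out, nrow(p), ncol(p))
  out
}

#' Thresholds for the rule-based substrate classifier
#'
#' Encodes the manual-mapping decision rules: soft seabed is flat
#' (slope below `soft_slope_max`) with spatially uniform backscatter inside
#' `soft_bs_band`; hard seabed is a raised feature (`hard_relief` metres above
#' the local median seabed) with flank gradients in `hard_gradient`, high
#' backscatter (above `hard_bs_min`) and a footprint of at least
#' `hard_min_area`; everything else — locally irregular seabed of modest
#' vertical range — is mixed.
#'
#' @param soft_slope_max degrees (default 1).
#' @param soft_bs_band dB interval (default c(-30, -25)).
#' @param hard_relief metres above the local median (default c(1, 5)).
#' @param hard_gradient degrees (default c(5, 15)).
#' @param hard_bs_min dB (default -25).
#' @param hard_min_area square metres (default 100).
#' @param mixed_relief_max metres (default 2).
#' @param relief_window moving-window width in cells for the local median
#'   datum (default 25).
#' @return A `rule_thresholds` list.
#' @export
rule_thresholds <- function(soft_slope_max = 1,
                            soft_bs_band = c(-30, -25),
                            hard_relief = c(1, 5),
                            hard_gradient = c(5, 15),
                            hard_bs_min = -25,
                            hard_min_area = 100,
                            mixed_relief_max = 2,
                            relief_window = 25L) {
  if (soft_slope_max <= 0) stop("soft_slope_max must be positive", call. = FALSE)
  if (hard_min_area <= 0) stop("hard_min_area must be positive", call. = FALSE)
  structure(list(soft_slope_max = soft_slope_max, soft_bs_band = soft_bs_band,
                 hard_relief = hard_relief, hard_gradient = hard_gradient,
                 hard_bs_min = hard_bs_min, hard_min_area = hard_min_area,
                 mixed_relief_max = mixed_relief_max,
                 relief_window = as.integer(relief_window)),
            class = "rule_thresholds")
}

# Relief above the local seabed datum: depth of the median cell in a
# relief_window x relief_window moving block minus the cell's own depth
# (positive where the cell rises above its surroundings).
local_relief <- function(depth, window) {
  nr <- nrow(depth); nc <- ncol(depth)
  half <- max(1L, window %/% 2L)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    jc <- max(1L, j - half):min(nc, j + half)
    block <- depth[, jc, drop = FALSE]
    for (i in seq_len(nr)) {
      ic <- max(1L, i - half):min(nr, i + half)
      out[i, j] <- stats::median(block[ic, ]) - depth[i, j]
    }
  }
  out
}

#' Rule-based substrate classification
#'
#' Deterministic per-cell plus connected-component implementation of the
#' manual-mapping rules. Hard candidates are cells whose relief above the
#' local median seabed lies within `hard_relief` and whose backscatter
#' exceeds `hard_bs_min`; candidate cells are grouped into 4-connected
#' components, and a component is confirmed hard only if its area reaches
#' `hard_min_area` and it exhibits flank gradients of at least
#' `hard_gradient[1]` (the gradient criterion describes the raised feature,
#' not every cell on its flat top, so it is applied at component level).
#' Among the remaining cells, soft requires slope below `soft_slope_max` and
#' backscatter inside `soft_bs_band`; everything else is mixed. The
#' classifier is total: every cell receives a label.
#'
#' @param depth_grid,slope_grid,backscatter_grid co-registered matrices.
#' @param thresholds a [rule_thresholds()] object.
#' @param cell_size cell edge in metres (for the component-area rule).
#' @return Character matrix of `"hard"`, `"mixed"`, `"soft"`.
#' @export
rule_classify <- function(depth_grid, slope_grid, backscatter_grid,
                          thresholds = rule_thresholds(), cell_size = 1) {
  if (!all(dim(depth_grid) == dim(slope_grid)) ||
      !all(dim(depth_grid) == dim(backscatter_grid)))
    stop("grids must share dimensions", call. = FALSE)
  th <- thresholds
  relief <- local_relief(depth_grid, th$relief_window)
  cand <- relief >= th$hard_relief[1] & relief <= th$hard_relief[2] &
    backscatter_grid > th$hard_bs_min
  out <- matrix(NA_character_, nrow(depth_grid), ncol(depth_grid))
  lab <- label_components(cand)
  cell_area <- cell_size^2
  if (max(lab) > 0) {
    for (cc in seq_len(max(lab))) {
      cells <- lab == cc
      ok_area <- sum(cells) * cell_area >= th$hard_min_area
      ok_grad <- max(slope_grid[cells]) >= th$hard_gradient[1]
      out[cells] <- if (ok_area && ok_grad) "hard" else "mixed"
    }
  }
  rest <- is.na(out)
  soft <- rest & slope_grid < th$soft_slope_max &
    backscatter_grid >= th$soft_bs_band[1] &
    backscatter_grid <= th$soft_bs_band[2]
  out[soft] <- "soft"
  out[is.na(out)] <- "mixed"
  out
}

#' Per-site substrate proportions and rescaled class areas
#'
#' Tabulates the class composition of the cells inside a site's observed
#' swath and rescales the class areas to a standard site area (default
#' 0.04 km^2) so that sites mapped with different swath widths carry equal
#' weight in design-based estimation.
#'
#' @param class_raster character matrix of class labels.
#' @param site_mask logical matrix (same shape) marking the site's cells,
#'   or a vector of cell indices.
#' @param standard_area_km2 standardized site area (default 0.04).
#' @return List with `proportions` (named, sums to 1) and `areas_km2`
#'   (named, sums to `standard_area_km2`).
#' @export
site_class_proportions <- function(class_raster, site_mask,
                                   standard_area_km2 = 0.04) {
  cls <- class_raster[site_mask]
  if (length(cls) == 0) stop("empty site mask", call. = FALSE)
  lv <- c("hard", "mixed", "soft")
  prop <- as.vector(table(factor(cls, levels = lv))) / length(cls)
  names(prop) <- lv
  list(proportions = prop, areas_km2 = prop * standard_area_km2)
}

# default dominant/subdominant consolidation table
default_label_rules <- function() {
  hard_labels <- c("rock", "boulder", "cobble")
  soft_labels <- c("sand", "mud", "pebble_gravel", "none")
  list(hard = hard_labels, soft = soft_labels)
}

#' Consolidate dominant/subdominant imagery labels to hard / mixed / soft
#'
#' Maps pairs of physical substrate labels scored from seabed imagery
#' (dominant and subdominant category per image) to the three-class scheme:
#' both hard-type labels give hard; a soft-type dominant with a soft-type (or
#' absent) subdominant gives soft; any hard/soft combination gives mixed.
#'
#' @param dominant,subdominant character vectors of labels from the
#'   configured vocabulary (use `"none"` for an absent subdominant).
#' @param rules list with character vectors `hard` and `soft` defining the
#'   vocabulary; defaults cover rock/boulder/cobble vs sand/mud/pebble_gravel.
#' @return Character vector of `"hard"`, `"mixed"`, `"soft"`.
#' @export
map_image_labels <- function(dominant, subdominant,
                             rules = default_label_rules()) {
  vocab <- c(rules$hard, rules$soft)
  bad <- setdiff(unique(c(dominant, subdominant)), vocab)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "),
         "; vocabulary is: ", paste(vocab, collapse = ", "), call. = FALSE)
  dh <- dominant %in% rules$hard
  sh <- subdominant %in% rules$hard
  s_none <- subdominant == "none"
  ifelse(dh & (sh | s_none), "hard",
         ifelse(!dh & (!sh | s_none), "soft", "mixed"))
}
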