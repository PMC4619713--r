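#' Candidate-site frame over a seascape
#'
#' Tiles the seascape with non-overlapping square candidate sites of the
#' standard survey footprint (default 200 m x 200 m = 0.04 km^2) and returns
#' them as a [sampling_frame()] of site centres. The block geometry is kept
#' in the `"blocks"` attribute so per-site class compositions can be read off
#' any co-registered raster.
#'
#' @param truth a `seascape` (or any object with `$config`).
#' @param site_edge_m site edge length in metres; must be a multiple of the
#'   cell size.
#' @param pi optional relative inclusion intensities per site.
#' @return A `sampling_frame` with one unit per candidate site.
#' @export
site_frame <- function(truth, site_edge_m = 200, pi = NULL) {
  cfg <- truth$config
  bc <- site_edge_m / cfg$cell_size
  if (abs(bc - round(bc)) > 1e-9)
    stop("site_edge_m must be a multiple of the cell size", call. = FALSE)
  bc <- as.integer(round(bc))
  nbx <- cfg$grid_nx %/% bc
  nby <- cfg$grid_ny %/% bc
  if (nbx < 1 || nby < 1) stop("site footprint larger than the grid",
                               call. = FALSE)
  bx <- rep(seq_len(nbx), each = nby)
  by <- rep(seq_len(nby), times = nbx)
  cx <- (bx - 0.5) * site_edge_m
  cy <- (by - 0.5) * site_edge_m
  fr <- sampling_frame(cx, cy, pi = pi)
  attr(fr, "blocks") <- data.frame(unit_id = fr$unit_id,
                                   row0 = (by - 1L) * bc + 1L,
                                   col0 = (bx - 1L) * bc + 1L,
                                   n_cells = bc)
  attr(fr, "site_edge_m") <- site_edge_m
  fr
}

#' Class composition of every candidate site in a frame
#'
#' Reads the hard/mixed/soft proportions of each candidate site's footprint
#' off a classified (or ground-truth) raster.
#'
#' @param class_raster character matrix of class labels, co-registered with
#'   the seascape the frame was built on.
#' @param frame a [site_frame()].
#' @return Numeric matrix, one row per frame unit, columns `prop_hard`,
#'   `prop_mixed`, `prop_soft`.
#' @export
frame_class_proportions <- function(class_raster, frame) {
  blocks <- attr(frame, "blocks")
  if (is.null(blocks)) stop("frame has no block geometry; use site_frame()",
                            call. = FALSE)
  out <- matrix(NA_real_, nrow(blocks), 3,
                dimnames = list(NULL, c("prop_hard", "prop_mixed", "prop_soft")))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    rows <- b$row0:(b$row0 + b$n_cells - 1L)
    cols <- b$col0:(b$col0 + b$n_cells - 1L)
    cls <- class_raster[rows, cols]
    out[i, ] <- c(mean(cls == "hard"), mean(cls == "mixed"),
                  mean(cls == "soft"))
  }
  out
}

#' Assemble site records for design-based estimation
#'
#' Joins a drawn site set (e.g. a master-sample prefix) with per-site class
#' proportions read from a raster, applying the realized-effort inclusion
#' adjustment, ready for [ht_category_estimate()].
#'
#' @param sites a [grts_master()] or [prefix_subset()] result.
#' @param frame the [site_frame()] the sites were drawn from.
#' @param class_raster classified (or truth) raster.
#' @param n_planned,n_realized planned and realized site counts for the
#'   inclusion adjustment; defaults treat the visited set as planned.
#' @return data.frame `site_id`, `x`, `y`, `pi`, `prop_hard`, `prop_mixed`,
#'   `prop_soft`.
#' @export
site_records <- function(sites, frame, class_raster,
                         n_planned = nrow(sites), n_realized = nrow(sites)) {
  props <- frame_class_proportions(class_raster, frame)
  idx <- match(sites$unit_id, frame$unit_id)
  pi_adj <- adjust_inclusion(sites$pi, n_planned, n_realized)
  data.frame(site_id = sites$unit_id, x = sites$x, y = sites$y, pi = pi_adj,
             prop_hard = props[idx, 1], prop_mixed = props[idx, 2],
             prop_soft = props[idx, 3])
}

#' Site-level mean biota cover over a frame
#'
#' Averages a seascape's per-cell biota cover over each candidate site's
#' footprint, for every group.
#'
#' @param truth a `seascape` with a `biota` layer.
#' @param frame a [site_frame()] built on the same seascape.
#' @return Numeric matrix, frame units by groups.
#' @export
frame_biota_cover <- function(truth, frame) {
  blocks <- attr(frame, "blocks")
  groups <- names(truth$biota)
  out <- matrix(NA_real_, nrow(blocks), length(groups),
                dimnames = list(NULL, groups))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    rows <- b$row0:(b$row0 + b$n_cells - 1L)
    cols <- b$col0:(b$col0 + b$n_cells - 1L)
    for (g in seq_along(groups))
      out[i, g] <- mean(truth$biota[[g]][rows, cols])
  }
  out
}
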