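#' Configuration for a synthetic shelf seascape
#'
#' Builds the parameter set that drives [generate_seascape()]. Defaults emulate
#' a temperate continental-shelf seascape: a gentle cross-shelf depth gradient,
#' patches of low-profile reef (1-5 m relief) surrounded by a "mixed" halo of
#' sand-veneered reef, class-dependent multibeam backscatter (soft sediment
#' around -25 to -30 dB, hard reef above -25 dB), class-dependent angular
#' response curves, and zero-inflated sessile biota cover concentrated on
#' reef with macroalgae restricted to shallow (< 50 m) cells.
#'
#' @param grid_nx,grid_ny number of grid cells in x and y.
#' @param cell_size cell edge length in metres.
#' @param depth_range numeric length 2, shallow and deep limits in metres
#'   (positive down); depth increases linearly along x with smooth undulation.
#' @param reef_fraction,mixed_fraction target fractions of hard and mixed
#'   cells; the remainder is soft. Must satisfy `reef_fraction +
#'   mixed_fraction <= 1`.
#' @param reef_relief numeric length 2, the range (m) by which hard reef cells
#'   rise above the surrounding seabed.
#' @param mixed_relief_max maximum relief (m) of mixed cells.
#' @param backscatter_params named list per class (`hard`, `mixed`, `soft`)
#'   of `c(mean, sd)` backscatter in dB.
#' @param arc_params named list per class of `c(offset, amplitude, decay)`:
#'   the noiseless angular response curve is
#'   `offset + amplitude * exp(-angle / decay)` dB. `noise_sd` is the additive
#'   per-angle noise standard deviation in dB.
#' @param arc_angles incidence-angle grid in degrees (ascending).
#' @param arc_noise_sd additive ARC noise sd in dB.
#' @param biota_params named list per group; each group is a named list per
#'   class of `c(occupancy, mean_cover)`. Cover is Bernoulli(occupancy) times
#'   a Beta draw with the given mean.
#' @param macroalgae_depth_limit depth (m) below which macroalgae cannot grow.
#' @param field_smoothness smoothing length (cells) of the latent reef field;
#'   the default (24 cells = 600 m at the default resolution) yields
#'   kilometre-scale reef complexes of the kind low-profile shelf reefs form.
#' @param undulation_m standard deviation (m) of the gentle bathymetric
#'   undulation superimposed on the regional gradient.
#' @param seed integer seed governing all stochastic layers.
#' @return An object of class `seascape_config` (a named list).
#' @export
seascape_config <- function(grid_nx = 400L, grid_ny = 400L,
                            cell_size = 25,
                            depth_range = c(40, 160),
                            reef_fraction = 0.10,
                            mixed_fraction = 0.20,
                            reef_relief = c(1, 5),
                            mixed_relief_max = 0.9,
                            backscatter_params = list(
                              hard  = c(mean = -21.0, sd = 1.0),
                              mixed = c(mean = -24.0, sd = 1.0),
                              soft  = c(mean = -27.5, sd = 1.0)
                            ),
                            arc_params = list(
                              hard  = c(offset = -24, amplitude = 8,  decay = 40),
                              mixed = c(offset = -26, amplitude = 9.5, decay = 36),
                              soft  = c(offset = -34, amplitude = 10, decay = 12)
                            ),
                            arc_angles = seq(1, 60, by = 1),
                            arc_noise_sd = 0.5,
                            biota_params = list(
                              bryozoa = list(
                                soft = c(occupancy = 0.15, mean_cover = 0.05),
                                mixed = c(occupancy = 0.60, mean_cover = 0.20),
                                hard = c(occupancy = 0.70, mean_cover = 0.25)),
                              sponges = list(
                                soft = c(occupancy = 0.10, mean_cover = 0.03),
                                mixed = c(occupancy = 0.50, mean_cover = 0.10),
                                hard = c(occupancy = 0.60, mean_cover = 0.15)),
                              cnidaria = list(
                                soft = c(occupancy = 0.05, mean_cover = 0.02),
                                mixed = c(occupancy = 0.30, mean_cover = 0.05),
                                hard = c(occupancy = 0.40, mean_cover = 0.08)),
                              macroalgae = list(
                                soft = c(occupancy = 0.02, mean_cover = 0.02),
                                mixed = c(occupancy = 0.40, mean_cover = 0.30),
                                hard = c(occupancy = 0.30, mean_cover = 0.20))
                            ),
                            macroalgae_depth_limit = 50,
                            field_smoothness = 24,
                            undulation_m = 0.4,
                            seed = 1L) {
  cfg <- list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
              cell_size = cell_size, depth_range = depth_range,
              reef_fraction = reef_fraction, mixed_fraction = mixed_fraction,
              reef_relief = reef_relief, mixed_relief_max = mixed_relief_max,
              backscatter_params = backscatter_params,
              arc_params = arc_params, arc_angles = arc_angles,
              arc_noise_sd = arc_noise_sd, biota_params = biota_params,
              macroalgae_depth_limit = macroalgae_depth_limit,
              field_smoothness = field_smoothness,
              undulation_m = undulation_m, seed = as.integer(seed))
  validate_seascape_config(cfg)
  class(cfg) <- "seascape_config"
  cfg
}

validate_seascape_config <- function(cfg) {
  if (cfg$grid_nx <= 0L || cfg$grid_ny <= 0L)
    stop("grid dimensions must be positive", call. = FALSE)
  if (cfg$cell_size <= 0)
    stop("cell_size must be positive", call. = FALSE)
  if (cfg$depth_range[1] >= cfg$depth_range[2])
    stop("depth_range must be (min, max) with min < max", call. = FALSE)
  fr <- c(cfg$reef_fraction, cfg$mixed_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("reef_fraction and mixed_fraction must be in [0,1] and sum to <= 1",
         call. = FALSE)
  if (length(cfg$arc_angles) < 1)
    stop("arc_angles must be non-empty", call. = FALSE)
  invisible(cfg)
}

#' Generate a synthetic seascape with known ground truth
#'
#' Produces co-registered grids of depth, slope, backscatter and true
#' substrate class, plus per-cell angular response curves and per-group
#' sessile-biota cover. The substrate field is built by thresholding a
#' smoothed Gaussian random field at the quantiles implied by the configured
#' class fractions: the upper tail forms connected hard-reef cores and the
#' band below it forms the mixed (sand-veneer) halo that naturally wraps the
#' cores, so realized class fractions match the targets up to ties.
#'
#' All randomness is governed by `config$seed` through per-layer sub-streams,
#' so the same configuration always yields a bit-identical seascape.
#'
#' @param config a [seascape_config()] object.
#' @return An object of class `seascape`: a list with matrices `depth`,
#'   `slope` (degrees), `backscatter` (dB), `class` (character, one of
#'   `"hard"`, `"mixed"`, `"soft"`), an ARC matrix `arc` (cells x angles, in
#'   column-major grid order), a list `biota` of per-group cover matrices,
#'   and the `config`. Matrices are `grid_ny` rows by `grid_nx` columns; cell
#'   centres are at `(col - 0.5) * cell_size`, `(row - 0.5) * cell_size`.
#' @examples
#' sc <- generate_seascape(seascape_config(grid_nx = 60, grid_ny = 60, seed = 7))
#' table(sc$class) / length(sc$class)
#' @export
generate_seascape <- function(config) {
  validate_seascape_config(config)
  nx <- config$grid_nx; ny <- config$grid_ny

  # latent reef field: smoothed white noise, thresholded at class quantiles
  set.seed(derive_seed(config$seed, 1L))
  field <- smooth_field(matrix(stats::rnorm(nx * ny), ny, nx),
                        config$field_smoothness)
  q_hard <- stats::quantile(field, 1 - config$reef_fraction, names = FALSE)
  q_mixed <- stats::quantile(field,
                             1 - config$reef_fraction - config$mixed_fraction,
                             names = FALSE)
  cls <- matrix("soft", ny, nx)
  cls[field > q_mixed] <- "mixed"
  if (config$reef_fraction > 0) cls[field > q_hard] <- "hard"
  if (config$reef_fraction + config$mixed_fraction <= 0) cls[] <- "soft"

  # bathymetry: linear cross-shelf gradient + gentle undulation - reef relief
  set.seed(derive_seed(config$seed, 2L))
  xfrac <- matrix(rep((seq_len(nx) - 0.5) / nx, each = ny), ny, nx)
  depth <- config$depth_range[1] + diff(config$depth_range) * xfrac
  und <- smooth_field(matrix(stats::rnorm(nx * ny), ny, nx),
                      config$field_smoothness * 2)
  und <- und / max(stats::sd(und), 1e-12) * config$undulation_m
  depth <- depth + und
  relief <- matrix(0, ny, nx)
  hard <- cls == "hard"
  if (any(hard)) {
    # relief scales with how far the latent field exceeds the hard threshold
    h <- (field[hard] - q_hard) / max(max(field) - q_hard, 1e-12)
    relief[hard] <- config$reef_relief[1] + diff(config$reef_relief) * h
  }
  mixed <- cls == "mixed"
  if (any(mixed)) {
    m <- (field[mixed] - q_mixed) / max(q_hard - q_mixed, 1e-12)
    relief[mixed] <- config$mixed_relief_max * m
  }
  depth <- depth - relief

  slope <- slope_from_depth(depth, config$cell_size)

  # backscatter: class mean + iid dB noise
  set.seed(derive_seed(config$seed, 3L))
  bs <- matrix(NA_real_, ny, nx)
  for (k in c("hard", "mixed", "soft")) {
    idx <- cls == k
    if (any(idx)) {
      p <- config$backscatter_params[[k]]
      bs[idx] <- stats::rnorm(sum(idx), p[["mean"]], p[["sd"]])
    }
  }

  truth <- structure(list(depth = depth, slope = slope, backscatter = bs,
                          class = cls, arc = NULL, biota = NULL,
                          config = config),
                     class = "seascape")
  truth$arc <- simulate_arc_field(truth, config)
  truth$biota <- simulate_biota(truth, config)
  truth
}

# Slope in degrees from a depth grid by central differences
# (one-sided at the boundary rows/columns).
slope_from_depth <- function(depth, cell_size) {
  nr <- nrow(depth); nc <- ncol(depth)
  ddx <- depth
  if (nc >= 3) {
    ddx[, 2:(nc - 1)] <- (depth[, 3:nc] - depth[, 1:(nc - 2)]) / (2 * cell_size)
  }
  ddx[, 1] <- (depth[, min(2, nc)] - depth[, 1]) / cell_size
  ddx[, nc] <- (depth[, nc] - depth[, max(nc - 1, 1)]) / cell_size
  ddy <- depth
  if (nr >= 3) {
    ddy[2:(nr - 1), ] <- (depth[3:nr, ] - depth[1:(nr - 2), ]) / (2 * cell_size)
  }
  ddy[1, ] <- (depth[min(2, nr), ] - depth[1, ]) / cell_size
  ddy[nr, ] <- (depth[nr, ] - depth[max(nr - 1, 1), ]) / cell_size
  atan(sqrt(ddx^2 + ddy^2)) * 180 / pi
}

#' Simulate per-cell angular response curves
#'
#' Each cell receives a backscatter-versus-incidence-angle curve drawn from
#' its substrate class's decay family `offset + amplitude * exp(-angle/decay)`
#' plus additive Gaussian noise. Under the default parameters the hard-class
#' mean curve lies above the soft-class mean curve at every angle and decays
#' more slowly, mirroring the stronger, flatter angular response of rock.
#'
#' @param truth a `seascape` with a populated `class` grid.
#' @param config the corresponding [seascape_config()].
#' @return Numeric matrix, one row per cell (column-major grid order), one
#'   column per angle in `config$arc_angles`; the angle grid is stored in
#'   attribute `"angles"`.
#' @export
simulate_arc_field <- function(truth, config) {
  if (length(config$arc_angles) < 1) stop("empty angle grid", call. = FALSE)
  cls <- as.vector(truth$class)
  na <- length(config$arc_angles)
  set.seed(derive_seed(config$seed, 4L))
  arc <- matrix(NA_real_, length(cls), na)
  for (k in c("hard", "mixed", "soft")) {
    idx <- which(cls == k)
    if (!length(idx)) next
    p <- config$arc_params[[k]]
    base <- p[["offset"]] + p[["amplitude"]] * exp(-config$arc_angles / p[["decay"]])
    noise <- matrix(stats::rnorm(length(idx) * na, 0, config$arc_noise_sd),
                    length(idx), na)
    arc[idx, ] <- matrix(base, length(idx), na, byrow = TRUE) + noise
  }
  attr(arc, "angles") <- config$arc_angles
  arc
}

#' Simulate zero-inflated sessile biota cover
#'
#' Cover for each group/cell is `Bernoulli(occupancy) * Beta` with the
#' configured class-dependent occupancy and mean cover (Beta shape1 fixed at
#' 2), reproducing the strong zero-inflation of benthic imagery scores.
#' Macroalgae cover is forced to zero wherever depth exceeds
#' `macroalgae_depth_limit`.
#'
#' @inheritParams simulate_arc_field
#' @return Named list of per-group cover matrices (same shape as the grids),
#'   values in `[0, 1]`.
#' @export
simulate_biota <- function(truth, config) {
  cls <- as.vector(truth$class)
  known <- c("hard", "mixed", "soft")
  for (g in names(config$biota_params)) {
    if (!all(names(config$biota_params[[g]]) %in% known))
      stop("unknown class name in biota_params for group '", g, "'",
           call. = FALSE)
  }
  set.seed(derive_seed(config$seed, 5L))
  out <- list()
  for (g in names(config$biota_params)) {
    cov <- numeric(length(cls))
    for (k in known) {
      idx <- which(cls == k)
      if (!length(idx)) next
      p <- config$biota_params[[g]][[k]]
      if (is.null(p)) next
      occ <- p[["occupancy"]]; m <- p[["mean_cover"]]
      on <- stats::rbinom(length(idx), 1L, occ) == 1L
      if (any(on) && m > 0) {
        a <- 2; b <- a * (1 - m) / m
        cov[idx[on]] <- stats::rbeta(sum(on), a, b)
      }
    }
    cov <- matrix(cov, nrow(truth$class), ncol(truth$class))
    if (g == "macroalgae") cov[truth$depth > config$macroalgae_depth_limit] <- 0
    out[[g]] <- cov
  }
  out
}

#' @export
print.seascape <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic seascape:", cfg$grid_ny, "x", cfg$grid_nx, "cells at",
      cfg$cell_size, "m\n")
  cat(sprintf("  extent: %.2f x %.2f km, depth %.1f-%.1f m\n",
              cfg$grid_nx * cfg$cell_size / 1000,
              cfg$grid_ny * cfg$cell_size / 1000,
              min(x$depth), max(x$depth)))
  fr <- table(factor(x$class, levels = c("hard", "mixed", "soft")))
  fr <- round(100 * fr / sum(fr), 1)
  cat(sprintf("  substrate: hard %.1f%%, mixed %.1f%%, soft %.1f%%\n",
              fr[["hard"]], fr[["mixed"]], fr[["soft"]]))
  cat("  layers: depth, slope, backscatter, class,",
      ncol(x$arc), "ARC angles,", length(x$biota), "biota groups\n")
  invisible(x)
}

#' @export
plot.seascape <- function(x, layer = c("class", "depth", "backscatter", "slope"),
                          ...) {
  layer <- match.arg(layer)
  cfg <- x$config
  xs <- (seq_len(cfg$grid_nx) - 0.5) * cfg$cell_size
  ys <- (seq_len(cfg$grid_ny) - 0.5) * cfg$cell_size
  if (layer == "class") {
    z <- matrix(match(x$class, c("soft", "mixed", "hard")),
                nrow(x$class), ncol(x$class))
    graphics::image(xs, ys, t(z), col = c("khaki", "orange", "firebrick"),
                    xlab = "x (m)", ylab = "y (m)", main = "substrate class", ...)
  } else {
    graphics::image(xs, ys, t(x[[layer]]), col = grDevices::hcl.colors(64),
                    xlab = "x (m)", ylab = "y (m)", main = layer, ...)
  }
  invisible(x)
}
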