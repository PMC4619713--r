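#' Local neighborhood variance estimator
#'
#' Variance estimator for totals under spatially balanced designs. Each
#' sampled site's neighborhood `D(i)` is itself plus its `nbh - 1` nearest
#' sampled sites; neighborhood weights start uniform and are doubly smoothed
#' by iterative row/column normalization until row sums are exactly 1 and
#' column sums are within tolerance of 1.
#' The estimator contrasts each weighted expansion term `t_j = z_j / pi_j`
#' with its local weighted mean:
#' \deqn{\hat V = \sum_i \sum_{j \in D(i)} w_{ij} (t_j - \bar t_i)^2,\qquad
#'       \bar t_i = \sum_{k \in D(i)} w_{ik} t_k.}
#' The sum is scaled by the small-neighborhood factor `nbh / (nbh - 1)`,
#' which makes the estimator unbiased for spatially unstructured data (a
#' local mean over `nbh` sites absorbs `1/nbh` of each squared deviation,
#' exactly as a sample variance loses one degree of freedom). The estimator
#' is exactly zero when all `t_j` are equal and, unlike the
#' simple-random-sampling formula, credits the variance reduction a spatially
#' balanced sample achieves on spatially structured populations; on smooth
#' dominant classes it errs conservative.
#'
#' With fewer than `nbh` sites the estimator falls back to the SRS variance
#' formula `n * var(t)` with a warning.
#'
#' @param x,y site coordinates (distinct).
#' @param pi inclusion probabilities in (0, 1].
#' @param z site values (for a mean/ratio estimator, pass residuals).
#' @param nbh neighborhood size including self (default 5, i.e. self plus
#'   the 4 nearest sampled neighbours; calibrated by simulation so the
#'   estimator tracks the replicate variance of GRTS draws).
#' @param tol column-sum tolerance for the weight balancing (default 1e-7).
#' @param max_iter cap on balancing sweeps (default 2000).
#' @return The estimated variance of the total `sum(z_i / pi_i)` (>= 0).
#' @export
local_mean_variance <- function(x, y, pi, z, nbh = 5L, tol = 1e-7,
                                max_iter = 2000L) {
  n <- length(x)
  if (any(pi <= 0) || any(pi > 1)) stop("pi must lie in (0,1]", call. = FALSE)
  t_val <- z / pi
  if (n < nbh) {
    warning("fewer than ", nbh, " sites: falling back to the SRS variance")
    return(n * stats::var(t_val))
  }
  w <- neighborhood_weights(x, y, nbh = nbh, tol = tol, max_iter = max_iter)
  tbar <- as.vector(w %*% t_val)
  dev2 <- outer(rep(1, n), t_val) - tbar  # dev2[i, j] = t_j - tbar_i
  (nbh / (nbh - 1)) * sum(w * dev2^2)
}

#' Doubly smoothed neighborhood weights
#'
#' Builds the weight matrix used by [local_mean_variance()]: support on each
#' site plus its `nbh - 1` nearest sampled sites, symmetrized (if `j` is in
#' `i`'s neighborhood then `i` joins `j`'s) so the support admits a doubly
#' stochastic limit, uniform initial weights, then alternating row/column
#' (Sinkhorn) normalization ending on a row pass, so every row sums to
#' exactly 1 and every column sum is within `tol` of 1.
#'
#' @inheritParams local_mean_variance
#' @return An `n x n` weight matrix.
#' @export
neighborhood_weights <- function(x, y, nbh = 5L, tol = 1e-7, max_iter = 2000L) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  if (any(d[upper.tri(d)] == 0))
    stop("sites must have distinct coordinates", call. = FALSE)
  sup <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(min(nbh, n))]  # self first (distance 0)
    sup[i, nb] <- TRUE
  }
  sup <- sup | t(sup)   # symmetric support guarantees Sinkhorn convergence
  w <- sup / rowSums(sup)
  for (it in seq_len(max_iter)) {
    w <- t(t(w) / colSums(w))
    w <- w / rowSums(w)
    if (max(abs(colSums(w) - 1)) < tol) break
  }
  w
}

#' Design-based substrate percentage estimates with confidence intervals
#'
#' Horvitz-Thompson estimation in the Hajek (ratio) form for the percentage
#' of each substrate class across the sampling frame:
#' \deqn{\hat p_c = 100 \, \frac{\sum_i y_{ic}/\pi_i}{\sum_i 1/\pi_i},}
#' where `y_ic` is site `i`'s observed proportion of class `c` (on its
#' standardized 0.04 km^2 footprint) and `pi_i` its (realized-effort
#' adjusted) inclusion probability. The ratio form keeps the three class
#' estimates summing to exactly 100 even when the realized site count is
#' random. Standard errors come from [local_mean_variance()] applied to the
#' residuals `y_ic - \hat p_c / 100`; 95% intervals are normal-approximation
#' (`z = 1.96`), truncated to `[0, 100]`.
#'
#' @param sites data.frame with columns `x`, `y`, `pi` and the per-class
#'   proportions `prop_hard`, `prop_mixed`, `prop_soft` (each row summing
#'   to 1).
#' @param conf_z normal quantile for the interval half-width (default 1.96).
#' @return An object of class `ht_estimate`: a data.frame with one row per
#'   class (`category`, `estimate`, `se`, `lcb95`, `ucb95`), percentages in
#'   `[0, 100]`, with `coef()`, `confint()`, `print()` and `summary()`
#'   methods.
#' @examples
#' s <- data.frame(x = runif(10), y = runif(10), pi = rep(0.5, 10),
#'                 prop_hard = 0.1, prop_mixed = 0.2, prop_soft = 0.7)
#' ht_category_estimate(s)
#' @export
ht_category_estimate <- function(sites, conf_z = 1.96) {
  req <- c("x", "y", "pi", "prop_hard", "prop_mixed", "prop_soft")
  if (!all(req %in% names(sites)))
    stop("sites must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (nrow(sites) < 2) stop("need at least 2 sites", call. = FALSE)
  if (any(sites$pi <= 0) || any(sites$pi > 1) || any(!is.finite(sites$pi)))
    stop("inclusion probabilities must lie in (0, 1]", call. = FALSE)
  props <- as.matrix(sites[, c("prop_hard", "prop_mixed", "prop_soft")])
  if (any(abs(rowSums(props) - 1) > 1e-6))
    stop("per-site class proportions must sum to 1", call. = FALSE)
  d <- 1 / sites$pi
  Nhat <- sum(d)
  out <- data.frame(category = c("hard", "mixed", "soft"),
                    estimate = NA_real_, se = NA_real_,
                    lcb95 = NA_real_, ucb95 = NA_real_)
  for (k in 1:3) {
    yc <- props[, k]
    p_hat <- sum(yc * d) / Nhat          # proportion in [0,1]
    resid <- yc - p_hat
    v_tot <- if (stats::sd(resid) == 0) 0 else
      local_mean_variance(sites$x, sites$y, sites$pi, resid)
    se <- 100 * sqrt(max(v_tot, 0)) / Nhat
    est <- 100 * p_hat
    out$estimate[k] <- est
    out$se[k] <- se
    out$lcb95[k] <- max(0, est - conf_z * se)
    out$ucb95[k] <- min(100, est + conf_z * se)
  }
  structure(out, class = c("ht_estimate", "data.frame"),
            n_sites = nrow(sites), type = "percent")
}

#' Combine two-phase inclusion probabilities
#'
#' In two-phase sampling (e.g. biota imagery collected at a subset of the
#' phase-I sites, with probabilities amended to favour mixed reef) the
#' overall inclusion probability of a phase-II site is the product of its
#' phase-I probability and its conditional phase-II probability.
#'
#' @param pi_phase1 phase-I inclusion probabilities in (0, 1].
#' @param pi_phase2_given_1 conditional phase-II probabilities in (0, 1].
#' @return `pi_phase1 * pi_phase2_given_1`.
#' @export
two_phase_pi <- function(pi_phase1, pi_phase2_given_1) {
  if (any(pi_phase1 <= 0) || any(pi_phase2_given_1 <= 0))
    stop("inclusion probabilities must be positive", call. = FALSE)
  if (any(pi_phase1 > 1) || any(pi_phase2_given_1 > 1))
    stop("inclusion probabilities cannot exceed 1", call. = FALSE)
  pi_phase1 * pi_phase2_given_1
}

#' Phase-II inclusion probabilities favouring a habitat class
#'
#' Class-weighted conditional probabilities for selecting `n2` of the phase-I
#' sites, with the favoured class (default mixed reef) receiving `weight`
#' times the intensity of the others, normalized so the conditional
#' probabilities sum to `n2` (clamped at 1 with re-normalization).
#'
#' @param site_class character vector of phase-I site classes.
#' @param n2 phase-II sample size.
#' @param favored class label to upweight (default `"mixed"`).
#' @param weight intensity ratio favoured : other (default 3).
#' @return Conditional inclusion probabilities, one per phase-I site.
#' @export
phase2_weights <- function(site_class, n2, favored = "mixed", weight = 3) {
  w <- ifelse(site_class == favored, weight, 1)
  normalize_pi(w, n2)
}

#' Score 25-point image annotations into cover by group
#'
#' Converts point-intercept annotations (25 scored points per image, labels
#' given as hierarchical codes with `/`-separated levels, e.g.
#' `"biota/bryozoa/soft/foliose"`) into per-image percent-cover observations
#' aggregated to the requested hierarchy level. Aggregation truncates each
#' label to `level` components and sums hits, so child-level covers sum
#' exactly to their parent's cover. Labels outside the `biota/` subtree
#' (e.g. bare substrate) occupy points but contribute no biota group.
#' Site-level cover is the unweighted mean over the site's images.
#'
#' @param annotations data.frame with columns `site_id`, `image_id`, `label`;
#'   one row per scored point, exactly 25 rows per image.
#' @param level hierarchy level to aggregate to (number of label components
#'   retained), typically 4, 5 or 6.
#' @param points_per_image number of scored points each image must have.
#' @return List with `images` (data.frame `site_id`, `image_id`, `group`,
#'   `points_hit`, `cover`) and `sites` (data.frame `site_id`, `group`,
#'   `cover` averaged over the site's images).
#' @export
image_cover_scores <- function(annotations, level = 4L,
                               points_per_image = 25L) {
  req <- c("site_id", "image_id", "label")
  if (!all(req %in% names(annotations)))
    stop("annotations must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  img_key <- paste(annotations$site_id, annotations$image_id, sep = "\r")
  counts <- table(img_key)
  bad <- names(counts)[counts != points_per_image]
  if (length(bad))
    stop("image(s) without exactly ", points_per_image, " points: ",
         paste(gsub("\r", "/", bad), collapse = ", "), call. = FALSE)
  parts <- strsplit(annotations$label, "/", fixed = TRUE)
  trunc_label <- vapply(parts, function(p)
    paste(p[seq_len(min(level, length(p)))], collapse = "/"), character(1))
  is_biota <- vapply(parts, function(p) p[1] == "biota", logical(1))
  keep <- is_biota
  imgs <- unique(annotations[, c("site_id", "image_id")])
  groups <- sort(unique(trunc_label[keep]))
  if (!length(groups)) {
    images <- data.frame(site_id = character(0), image_id = character(0),
                         group = character(0), points_hit = integer(0),
                         cover = numeric(0))
    return(list(images = images,
                sites = data.frame(site_id = character(0),
                                   group = character(0), cover = numeric(0))))
  }
  tab <- table(img_key[keep], factor(trunc_label[keep], levels = groups))
  all_keys <- paste(imgs$site_id, imgs$image_id, sep = "\r")
  hits <- matrix(0L, length(all_keys), length(groups),
                 dimnames = list(all_keys, groups))
  hits[rownames(tab), ] <- tab
  images <- data.frame(
    site_id = rep(imgs$site_id, times = length(groups)),
    image_id = rep(imgs$image_id, times = length(groups)),
    group = rep(groups, each = nrow(imgs)),
    points_hit = as.vector(hits),
    cover = as.vector(hits) / points_per_image)
  agg <- stats::aggregate(cover ~ site_id + group, data = images, FUN = mean)
  list(images = images, sites = agg[order(agg$site_id, agg$group), ])
}

#' Design-based total area of sessile biota groups
#'
#' Expands site-level mean covers to a total habitat area over the sampling
#' frame using the Hajek ratio estimator with the two-phase inclusion
#' probabilities:
#' \deqn{\hat T_b = A \,\frac{\sum_i \bar c_{ib}/\pi^*_i}{\sum_i 1/\pi^*_i},}
#' where `A` is the frame area in km^2. Standard errors use
#' [local_mean_variance()] on the cover residuals; 95% intervals are normal
#' approximation with the lower bound truncated at 0. A group observed at no
#' site gets estimate 0 with interval (0, 0).
#'
#' @param site_cover data.frame `site_id`, `group`, `cover` (site-level mean
#'   covers, e.g. `image_cover_scores()$sites`).
#' @param sites data.frame `site_id`, `x`, `y`, `pi` with the overall
#'   (two-phase) inclusion probabilities.
#' @param frame_area_km2 total frame area in km^2.
#' @param conf_z normal quantile (default 1.96).
#' @return An `ht_estimate` data.frame: `category` (group), `estimate`
#'   (km^2), `se`, `lcb95`, `ucb95`.
#' @export
biota_total_area <- function(site_cover, sites, frame_area_km2,
                             conf_z = 1.96) {
  if (frame_area_km2 <= 0) stop("frame_area_km2 must be positive", call. = FALSE)
  if (any(sites$pi <= 0) || any(sites$pi > 1))
    stop("inclusion probabilities must lie in (0, 1]", call. = FALSE)
  d <- 1 / sites$pi
  Nhat <- sum(d)
  groups <- sort(unique(site_cover$group))
  out <- data.frame(category = groups, estimate = NA_real_, se = NA_real_,
                    lcb95 = NA_real_, ucb95 = NA_real_)
  for (k in seq_along(groups)) {
    cv <- site_cover$cover[site_cover$group == groups[k]][
      match(sites$site_id, site_cover$site_id[site_cover$group == groups[k]])]
    cv[is.na(cv)] <- 0
    if (all(cv == 0)) {
      out[k, c("estimate", "se", "lcb95", "ucb95")] <- c(0, 0, 0, 0)
      next
    }
    m_hat <- sum(cv * d) / Nhat
    resid <- cv - m_hat
    v_tot <- if (stats::sd(resid) == 0) 0 else
      local_mean_variance(sites$x, sites$y, sites$pi, resid)
    se <- frame_area_km2 * sqrt(max(v_tot, 0)) / Nhat
    est <- frame_area_km2 * m_hat
    out$estimate[k] <- est
    out$se[k] <- se
    out$lcb95[k] <- max(0, est - conf_z * se)
    out$ucb95[k] <- est + conf_z * se
  }
  structure(out, class = c("ht_estimate", "data.frame"),
            n_sites = nrow(sites), type = "area",
            frame_area_km2 = frame_area_km2)
}

#' @export
print.ht_estimate <- function(x, digits = 2, ...) {
  type <- attr(x, "type")
  unit <- if (identical(type, "percent")) "%" else "km^2"
  cat("Design-based GRTS estimates (", attr(x, "n_sites"), " sites)\n",
      sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %6.*f %s (%.*f, %.*f)\n", x$category[i],
                digits, x$estimate[i], unit,
                digits, x$lcb95[i], digits, x$ucb95[i]))
  }
  cat("Brackets: lower and upper 95% confidence bounds (truncated at the\n")
  cat("domain limits), from the local neighborhood variance estimator.\n")
  invisible(x)
}

#' @export
summary.ht_estimate <- function(object, ...) {
  print(object, ...)
  invisible(as.data.frame(object))
}

#' @export
coef.ht_estimate <- function(object, ...) {
  stats::setNames(object$estimate, object$category)
}

#' @export
confint.ht_estimate <- function(object, parm, level = 0.95, ...) {
  if (!missing(parm)) object <- object[object$category %in% parm, ]
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- pmax(if (identical(attr(object, "type"), "percent")) 0 else 0,
             object$estimate - z * object$se)
  hi <- object$estimate + z * object$se
  if (identical(attr(object, "type"), "percent")) hi <- pmin(100, hi)
  m <- cbind(lo, hi)
  dimnames(m) <- list(object$category,
                      paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %"))
  m
}
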