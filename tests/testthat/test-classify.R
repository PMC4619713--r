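make_curve <- function(int, angles = 1:10) arc_curve(angles, int)

test_that("the reference ARC is the pointwise mean of its training curves", {
  a <- make_curve(rep(-20, 10))
  b <- make_curve(rep(-30, 10))
  ref <- build_reference_arc(list(a, b))
  expect_equal(ref$intensities, rep(-25, 10))
  expect_equal(ref$n_training, 2)
  # averaging identical curves is idempotent
  ref2 <- build_reference_arc(list(a, a, a))
  expect_equal(ref2$intensities, a$intensities)
  expect_error(build_reference_arc(list(a)), "at least 2")
  expect_error(build_reference_arc(list(a, make_curve(rep(-20, 12), 1:12))),
               "common angle grid")
})

test_that("a 100-curve training draw from a 720 pool leaves 620 for validation", {
  set.seed(30)
  pool <- lapply(1:720, function(i) make_curve(rnorm(10, -25)))
  tr_idx <- sample(720, 100)
  ref <- build_reference_arc(pool[tr_idx])
  expect_equal(ref$n_training, 100)
  expect_length(setdiff(seq_along(pool), tr_idx), 620)
})

test_that("ks_phard is exact at identity and monotone in the KS distance", {
  set.seed(31)
  ref <- build_reference_arc(list(make_curve(-20 - 0.2 * (1:10)),
                                  make_curve(-20 - 0.2 * (1:10))))
  p_same <- ks_phard(make_curve(-20 - 0.2 * (1:10)), ref)
  expect_equal(attr(p_same, "D"), 0)
  expect_equal(as.numeric(p_same), 1)
  res <- t(vapply(1:40, function(i) {
    cv <- make_curve(-20 - 0.2 * (1:10) + rnorm(10, 0, 1))
    p <- ks_phard(cv, ref)
    c(D = attr(p, "D"), p = as.numeric(p))
  }, numeric(2)))
  ord <- order(res[, "D"])
  expect_true(all(diff(res[ord, "p"]) <= 1e-12))
  flat <- make_curve(rep(-25, 10))
  expect_error(ks_phard(flat, build_reference_arc(list(flat, flat))), "flat")
})

test_that("ks_phard agrees with the brute-force KS oracle", {
  set.seed(32)
  for (rep in 1:20) {
    i1 <- -25 + rnorm(12, sd = 2)
    i2 <- -25 + rnorm(12, sd = 2)
    ref <- build_reference_arc(list(arc_curve(1:12, i2), arc_curve(1:12, i2)))
    p <- ks_phard(arc_curve(1:12, i1), ref)
    orc <- oracle_ks_phard(i1, i2)
    expect_equal(attr(p, "D"), orc$D, tolerance = 1e-12)
    expect_equal(as.numeric(p), orc$p, tolerance = 1e-10)
  }
})

test_that("p-hard thresholds classify with an inclusive mixed band", {
  expect_equal(classify_phard(0.95), "hard")
  expect_equal(classify_phard(0.90), "mixed")
  expect_equal(classify_phard(0.10), "mixed")
  expect_equal(classify_phard(0.05), "soft")
  m <- classify_phard(matrix(c(0.95, 0.5, 0.05, 0.2), 2, 2))
  expect_true(is.matrix(m))
  expect_error(classify_phard(0.5, lo = 0.9, hi = 0.1), "less than")
})

test_that("IDW is exact at observations, symmetric at midpoints, and bounded", {
  obs <- data.frame(x = c(0, 10), y = c(0, 0), value = c(0.2, 0.8))
  out <- idw_interpolate(obs, grid_x = c(0, 5, 10), grid_y = 0)
  expect_equal(out$values[1, 1], 0.2)
  expect_equal(out$values[1, 3], 0.8)
  expect_equal(out$values[1, 2], 0.5)
  expect_equal(out$provenance[1, c(1, 3)], c("observed", "observed"))
  set.seed(33)
  for (rep in 1:20) {
    obs <- data.frame(x = runif(5, 0, 10), y = runif(5, 0, 10),
                      value = runif(5))
    out <- idw_interpolate(obs, grid_x = seq(0, 10, 2), grid_y = seq(0, 10, 2))
    expect_true(all(out$values >= min(obs$value) - 1e-12))
    expect_true(all(out$values <= max(obs$value) + 1e-12))
  }
  expect_error(idw_interpolate(data.frame(x = numeric(0), y = numeric(0),
                                          value = numeric(0)), 1, 1),
               "at least one")
})

test_that("rule classifier applies the soft, hard and minimum-area rules", {
  # 20 x 20 grid of 5 m cells; flat 50 m seabed
  n <- 20; cs <- 5
  depth <- matrix(50, n, n)
  slope <- matrix(0.5, n, n)
  bs <- matrix(-27, n, n)
  cls <- rule_classify(depth, slope, bs, rule_thresholds(), cs)
  expect_true(all(cls == "soft"))
  # 6-cell raised component: area 150 m^2, 3 m relief, 10 deg flank, -20 dB
  depth2 <- depth; slope2 <- slope; bs2 <- bs
  cells <- cbind(rep(10:11, 3), rep(9:11, each = 2))
  depth2[cells] <- 47
  slope2[cells] <- 10
  bs2[cells] <- -20
  cls2 <- rule_classify(depth2, slope2, bs2, rule_thresholds(), cs)
  expect_true(all(cls2[cells] == "hard"))
  expect_equal(cls2[1, 1], "soft")
  # same feature but only 2 cells (50 m^2): below the minimum area, demoted
  depth3 <- depth; slope3 <- slope; bs3 <- bs
  cells3 <- cbind(10:11, c(10, 10))
  depth3[cells3] <- 47; slope3[cells3] <- 10; bs3[cells3] <- -20
  cls3 <- rule_classify(depth3, slope3, bs3, rule_thresholds(), cs)
  expect_true(all(cls3[cells3] == "mixed"))
  expect_error(rule_classify(depth, slope[1:5, ], bs, rule_thresholds(), cs),
               "dimensions")
})

test_that("rule classifier recovers a well-separated seascape away from boundaries", {
  cfg <- seascape_config(grid_nx = 150, grid_ny = 150, cell_size = 2,
                         depth_range = c(40, 41), reef_relief = c(2, 4),
                         field_smoothness = 4, undulation_m = 0.05, seed = 11)
  sc <- generate_seascape(cfg)
  pred <- rule_classify(sc$depth, sc$slope, sc$backscatter, rule_thresholds(),
                        cfg$cell_size)
  cls <- sc$class; n <- nrow(cls)
  interior <- cls[c(1, 1:(n - 1)), ] == cls & cls[c(2:n, n), ] == cls &
    cls[, c(1, 1:(n - 1))] == cls & cls[, c(2:n, n)] == cls
  expect_gte(mean(pred[interior] == cls[interior]), 0.90)
  # repeated runs are identical (total, deterministic)
  expect_identical(pred, rule_classify(sc$depth, sc$slope, sc$backscatter,
                                       rule_thresholds(), cfg$cell_size))
})

test_that("ARC p-hard classifier recovers a well-separated seascape", {
  cfg <- seascape_config(grid_nx = 120, grid_ny = 120, cell_size = 25,
                         field_smoothness = 10, seed = 21)
  sc <- generate_seascape(cfg)
  set.seed(34)
  hard_cells <- which(as.vector(sc$class) == "hard")
  ref <- build_reference_arc(lapply(sample(hard_cells, 100), function(i)
    arc_curve(cfg$arc_angles, sc$arc[i, ], i)))
  p <- phard_field(sc$arc, ref)
  pred <- classify_phard(p)
  expect_gte(mean(pred == as.vector(sc$class)), 0.90)
})

test_that("site proportions sum to one and rescale to the standard area", {
  cls <- matrix("soft", 10, 10)
  out <- site_class_proportions(cls, matrix(TRUE, 10, 10))
  expect_equal(unname(out$proportions), c(0, 0, 1))
  expect_equal(unname(out$areas_km2["soft"]), 0.04)
  # half hard, half soft on a small observed swath
  cls2 <- matrix(rep(c("hard", "soft"), each = 50), 10, 10)
  out2 <- site_class_proportions(cls2, matrix(TRUE, 10, 10))
  expect_equal(unname(out2$areas_km2["hard"]), 0.02)
  set.seed(35)
  for (rep in 1:20) {
    cls3 <- matrix(sample(c("hard", "mixed", "soft"), 64, replace = TRUE), 8, 8)
    out3 <- site_class_proportions(cls3, matrix(TRUE, 8, 8))
    expect_equal(sum(out3$proportions), 1, tolerance = 1e-12)
    expect_equal(sum(out3$areas_km2), 0.04, tolerance = 1e-12)
  }
  expect_error(site_class_proportions(cls, matrix(FALSE, 10, 10)), "empty")
})

test_that("dominant/subdominant imagery labels map onto the three classes", {
  expect_equal(map_image_labels("sand", "sand"), "soft")
  expect_equal(map_image_labels("rock", "rock"), "hard")
  expect_equal(map_image_labels("sand", "rock"), "mixed")
  expect_equal(map_image_labels("rock", "sand"), "mixed")
  expect_equal(map_image_labels("sand", "none"), "soft")
  expect_equal(map_image_labels(c("rock", "mud"), c("boulder", "none")),
               c("hard", "soft"))
  expect_error(map_image_labels("granite", "sand"), "vocabulary")
})
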