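test_that("degenerate configuration yields an all-soft seascape", {
  sc <- generate_seascape(small_config(reef_fraction = 0, mixed_fraction = 0))
  expect_true(all(sc$class == "soft"))
})

test_that("soft-cell backscatter sits in the configured -30 to -25 dB band", {
  sc <- generate_seascape(small_config(seed = 3))
  m <- mean(sc$backscatter[sc$class == "soft"])
  expect_gt(m, -30)
  expect_lt(m, -25)
  # and acoustic separation is monotone: hard > soft on average
  expect_gt(mean(sc$backscatter[sc$class == "hard"]), m)
})

test_that("a fixed seed reproduces the seascape bit-identically", {
  cfg <- small_config(seed = 11)
  a <- generate_seascape(cfg)
  b <- generate_seascape(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("realized class fractions track the configured targets", {
  cfg <- seascape_config(grid_nx = 200, grid_ny = 200, cell_size = 25,
                         reef_fraction = 0.15, mixed_fraction = 0.25,
                         field_smoothness = 10, seed = 5)
  sc <- generate_seascape(cfg)
  fr <- table(factor(sc$class, levels = c("hard", "mixed", "soft"))) /
    length(sc$class)
  expect_lt(abs(fr[["hard"]] - 0.15), 0.05)
  expect_lt(abs(fr[["mixed"]] - 0.25), 0.05)
  expect_lt(abs(fr[["soft"]] - 0.60), 0.05)
})

test_that("slope grid agrees with central differences on the depth grid", {
  sc <- generate_seascape(small_config(seed = 2))
  cs <- sc$config$cell_size
  i <- 17L; j <- 23L
  ddx <- (sc$depth[i, j + 1] - sc$depth[i, j - 1]) / (2 * cs)
  ddy <- (sc$depth[i + 1, j] - sc$depth[i - 1, j]) / (2 * cs)
  expect_equal(sc$slope[i, j], atan(sqrt(ddx^2 + ddy^2)) * 180 / pi,
               tolerance = 1e-12)
})

test_that("reef cells rise above the surrounding seabed by the configured relief", {
  cfg <- small_config(seed = 9, reef_relief = c(2, 4))
  sc <- generate_seascape(cfg)
  # compare hard-cell depth with the no-reef depth surface of the same config
  flat <- generate_seascape(small_config(seed = 9, reef_relief = c(2, 4),
                                         reef_fraction = 0, mixed_fraction = 0))
  raised <- flat$depth[sc$class == "hard"] - sc$depth[sc$class == "hard"]
  expect_true(all(raised >= 2 - 1e-9))
  expect_true(all(raised <= 4 + 1e-9))
})

test_that("noiseless ARC field collapses to one curve per class, hard above soft", {
  cfg <- small_config(seed = 4, arc_noise_sd = 0)
  sc <- generate_seascape(cfg)
  hard <- sc$arc[as.vector(sc$class) == "hard", , drop = FALSE]
  soft <- sc$arc[as.vector(sc$class) == "soft", , drop = FALSE]
  expect_true(all(abs(sweep(hard, 2, hard[1, ])) < 1e-12))
  expect_true(all(abs(sweep(soft, 2, soft[1, ])) < 1e-12))
  # configured decay curves keep the hard response above soft at every angle
  expect_true(all(hard[1, ] >= soft[1, ]))
})

test_that("arc field generation is reproducible and rejects an empty angle grid", {
  cfg <- small_config(seed = 6)
  sc <- generate_seascape(cfg)
  expect_identical(simulate_arc_field(sc, cfg), simulate_arc_field(sc, cfg))
  bad <- cfg
  bad$arc_angles <- numeric(0)
  expect_error(simulate_arc_field(sc, bad), "empty")
})

test_that("biota cover is zero-inflated, bounded, and depth-limited", {
  cfg <- small_config(seed = 8)
  sc <- generate_seascape(cfg)
  for (g in names(sc$biota)) {
    expect_true(all(sc$biota[[g]] >= 0 & sc$biota[[g]] <= 1))
  }
  expect_true(all(sc$biota$macroalgae[sc$depth > cfg$macroalgae_depth_limit] == 0))
  # zero occupancy silences every group
  zp <- lapply(cfg$biota_params, function(g)
    lapply(g, function(p) c(occupancy = 0, mean_cover = p[["mean_cover"]])))
  sc0 <- generate_seascape(small_config(seed = 8, biota_params = zp))
  expect_true(all(vapply(sc0$biota, function(m) all(m == 0), logical(1))))
})

test_that("large-sample biota cover matches the configured class means", {
  # >= 1e5 cells, deep enough that the macroalgae depth cap is active
  cfg <- seascape_config(grid_nx = 350, grid_ny = 300, cell_size = 25,
                         field_smoothness = 10, seed = 13)
  sc <- generate_seascape(cfg)
  for (g in c("bryozoa", "sponges")) {
    for (k in c("soft", "mixed", "hard")) {
      p <- cfg$biota_params[[g]][[k]]
      expected <- p[["occupancy"]] * p[["mean_cover"]]
      got <- mean(sc$biota[[g]][sc$class == k])
      expect_lt(abs(got - expected), 0.01)
    }
  }
  # reef-associated cover orders soft <= mixed
  expect_lte(mean(sc$biota$bryozoa[sc$class == "soft"]),
             mean(sc$biota$bryozoa[sc$class == "mixed"]))
})

test_that("invalid configurations are rejected", {
  expect_error(seascape_config(grid_nx = 0), "positive")
  expect_error(seascape_config(cell_size = -1), "positive")
  expect_error(seascape_config(depth_range = c(100, 40)), "min < max")
  expect_error(seascape_config(reef_fraction = 0.7, mixed_fraction = 0.5),
               "sum")
  sc <- generate_seascape(small_config())
  bad <- small_config()
  bad$biota_params$bryozoa$granite <- c(occupancy = 1, mean_cover = 0.5)
  expect_error(simulate_biota(sc, bad), "unknown class")
})
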