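random_sites <- function(n, seed = 1) {
  set.seed(seed)
  p <- matrix(runif(3 * n), n, 3)
  p <- p / rowSums(p)
  data.frame(x = runif(n, 0, 1000), y = runif(n, 0, 1000),
             pi = runif(n, 0.05, 0.9),
             prop_hard = p[, 1], prop_mixed = p[, 2], prop_soft = p[, 3])
}

test_that("local variance is zero for constant fields and positive otherwise", {
  set.seed(40)
  x <- runif(20); y <- runif(20); pi <- rep(0.5, 20)
  expect_equal(local_mean_variance(x, y, pi, rep(0.3, 20) - 0.3), 0)
  expect_gt(local_mean_variance(x, y, pi, rnorm(20)), 0)
})

test_that("neighborhood weights are doubly balanced", {
  set.seed(41)
  x <- runif(30); y <- runif(30)
  w <- neighborhood_weights(x, y)
  expect_equal(rowSums(w), rep(1, 30), tolerance = 1e-12)
  expect_true(max(abs(colSums(w) - 1)) < 1e-6)
  expect_error(neighborhood_weights(c(1, 1, 2), c(1, 1, 2)), "distinct")
})

test_that("local variance tracks the SRS estimate for spatially random values", {
  set.seed(42)
  ratio <- vapply(1:200, function(r) {
    n <- 30
    x <- runif(n); y <- runif(n); pi <- rep(n / 100, n)
    z <- rnorm(n)
    t_val <- z / pi
    v_srs <- n * stats::var(t_val)
    local_mean_variance(x, y, pi, z) / v_srs
  }, numeric(1))
  expect_lt(abs(median(ratio) - 1), 0.2)
})

test_that("fewer than a neighborhood of sites falls back to SRS with a warning", {
  expect_warning(v <- local_mean_variance(c(0, 1, 2), c(0, 1, 0),
                                          rep(0.5, 3), c(1, 2, 3)),
                 "SRS")
  expect_equal(v, 3 * stats::var(c(1, 2, 3) / 0.5))
})

test_that("Hajek class estimates behave on constant and equal-weight inputs", {
  s <- data.frame(x = runif(6), y = runif(6), pi = rep(0.3, 6),
                  prop_hard = 0, prop_mixed = 0, prop_soft = 1)
  e <- ht_category_estimate(s)
  expect_equal(coef(e), c(hard = 0, mixed = 0, soft = 100))
  expect_equal(e$se, rep(0, 3))
  expect_equal(e$lcb95, e$estimate)
  s2 <- data.frame(x = c(0, 5, 9), y = c(1, 7, 3), pi = rep(0.5, 3),
                   prop_hard = c(0.2, 0.4, 0.6),
                   prop_mixed = c(0.5, 0.3, 0.1),
                   prop_soft = c(0.3, 0.3, 0.3))
  suppressWarnings(e2 <- ht_category_estimate(s2))
  expect_equal(unname(coef(e2)["hard"]), 40)
  expect_error(ht_category_estimate(s2[1, ]), "at least 2")
  bad <- s2; bad$prop_hard <- bad$prop_hard + 0.2
  expect_error(ht_category_estimate(bad), "sum to 1")
})

test_that("class percentage estimates always sum to one hundred", {
  for (r in 1:200) {
    e <- ht_category_estimate(random_sites(12, seed = r))
    expect_lt(abs(sum(e$estimate) - 100), 1e-9)
    expect_true(all(e$lcb95 >= 0 & e$ucb95 <= 100))
    expect_true(all(e$lcb95 <= e$estimate & e$estimate <= e$ucb95))
  }
})

test_that("two-phase probabilities multiply and respect a census phase", {
  expect_equal(two_phase_pi(0.5, 0.5), 0.25)
  expect_equal(two_phase_pi(0.37, 1.0), 0.37)
  expect_true(all(two_phase_pi(c(0.2, 0.8), c(0.5, 0.3)) <=
                    pmin(c(0.2, 0.8), c(0.5, 0.3))))
  expect_error(two_phase_pi(0, 0.5), "positive")
  expect_error(two_phase_pi(0.5, 1.2), "exceed")
})

test_that("census phase-II reduces two-phase estimates to single-phase exactly", {
  s <- random_sites(15, seed = 7)
  e1 <- ht_category_estimate(s)
  s2 <- s
  s2$pi <- two_phase_pi(s$pi, rep(1, 15))
  e2 <- ht_category_estimate(s2)
  expect_identical(e1, e2)
})

test_that("phase-II class weighting matches amended inclusion probabilities", {
  set.seed(43)
  cls <- c(rep("mixed", 15), rep("soft", 25))
  w <- phase2_weights(cls, 11, weight = 3)
  expect_equal(sum(w), 11, tolerance = 1e-9)
  expect_equal(unique(w[cls == "mixed"]) / unique(w[cls == "soft"]), 3)
  # empirical class counts over replicate GRTS subsets track sum(pi) by class
  fr <- sampling_frame(runif(40, 0, 100), runif(40, 0, 100), pi = w)
  n_rep <- 2000
  n_mixed <- vapply(seq_len(n_rep), function(r) {
    m <- grts_master(fr, 11, seed = 50000 + r)
    sum(cls[m$unit_id] == "mixed")
  }, numeric(1))
  expected <- sum(w[cls == "mixed"])
  se <- stats::sd(n_mixed) / sqrt(n_rep)
  expect_lt(abs(mean(n_mixed) - expected), 3 * se + 0.05)
})

test_that("image point scores aggregate conservatively across CATAMI levels", {
  mk_img <- function(site, img, labels) {
    data.frame(site_id = site, image_id = img, label = labels)
  }
  bare <- mk_img("s1", "i1", rep("substrate/sand", 25))
  out <- image_cover_scores(bare, level = 4)
  expect_equal(nrow(out$images), 0)
  ann <- rbind(
    mk_img("s1", "i1", c(rep("biota/sponges/massive/simple", 5),
                         rep("substrate/sand", 20))),
    mk_img("s1", "i2", c(rep("biota/sponges/erect/branching", 10),
                         rep("biota/bryozoa/soft/foliose", 5),
                         rep("substrate/sand", 10))))
  lv4 <- image_cover_scores(ann, level = 4)
  i1 <- lv4$images[lv4$images$image_id == "i1", ]
  expect_equal(i1$cover[i1$group == "biota/sponges/massive/simple"], 0.2)
  # level-5 covers summed to their level-4 parent equal the level-4 cover
  lv5 <- image_cover_scores(ann, level = 5)
  lv4b <- image_cover_scores(ann, level = 4)
  for (img in c("i1", "i2")) {
    a5 <- lv5$images[lv5$images$image_id == img, ]
    a5$parent <- vapply(strsplit(a5$group, "/"), function(p)
      paste(p[1:min(4, length(p))], collapse = "/"), character(1))
    s5 <- tapply(a5$cover, a5$parent, sum)
    a4 <- lv4b$images[lv4b$images$image_id == img, ]
    for (g in a4$group[a4$cover > 0]) {
      expect_equal(unname(s5[g]), a4$cover[a4$group == g])
    }
  }
  short <- mk_img("s1", "i3", rep("biota/sponges", 24))
  expect_error(image_cover_scores(rbind(ann, short)), "i3")
})

test_that("biota totals expand cover to frame area with truncated intervals", {
  sites <- data.frame(site_id = paste0("s", 1:11),
                      x = runif(11, 0, 1000), y = runif(11, 0, 1000),
                      pi = rep(0.3, 11))
  zero <- data.frame(site_id = sites$site_id, group = "biota/bryozoa",
                     cover = 0)
  e0 <- biota_total_area(zero, sites, frame_area_km2 = 774)
  expect_equal(e0$estimate, 0)
  expect_equal(c(e0$lcb95, e0$ucb95), c(0, 0))
  unif <- data.frame(site_id = sites$site_id, group = "biota/sponges",
                     cover = 0.10)
  e1 <- biota_total_area(unif, sites, frame_area_km2 = 774)
  expect_equal(e1$estimate, 77.4)
  expect_equal(e1$se, 0)
  set.seed(44)
  noisy <- data.frame(site_id = rep(sites$site_id, 2),
                      group = rep(c("biota/bryozoa", "biota/sponges"), each = 11),
                      cover = c(rbeta(11, 0.3, 3), rbeta(11, 0.2, 5)))
  e2 <- biota_total_area(noisy, sites, frame_area_km2 = 774)
  expect_true(all(e2$lcb95 >= 0))
  expect_true(all(e2$estimate >= e2$lcb95 & e2$estimate <= e2$ucb95))
  expect_error(biota_total_area(unif, sites, frame_area_km2 = 0), "positive")
})

test_that("design-based estimates are unbiased for the seascape truth", {
  cs <- acceptance_coverage_sim()
  for (k in c("hard", "mixed", "soft")) {
    expect_lt(abs(cs$mean_estimate[k] - cs$truth_pct[k]), 1)
  }
})
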