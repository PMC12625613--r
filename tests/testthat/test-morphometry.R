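test_that("rectangle and disk widths match their analytic values", {
  m <- matrix(0L, 60, 240)
  m[21:40, 21:220] <- 1L  # 200 x 20 rectangle
  d <- tube_diameter(m, pixel_size = 1)
  expect_equal(d$mean_diameter_um, 20, tolerance = 1 / 20)  # 20 +/- 1
  expect_gt(d$n_sample_sites, 50)
  # filled disk: medial axis collapses to the center
  dk <- disk_mask(51, c(26, 26), 12)
  dd <- tube_diameter(dk)
  expect_lte(abs(dd$mean_diameter_um - 24), 2)
  expect_error(tube_diameter(matrix(0L, 5, 5)), "Empty")
})

test_that("clustered-nuclei exclusion removes sites, not width", {
  m <- matrix(0L, 60, 240)
  m[21:40, 21:220] <- 1L
  cluster <- rbind(c(30, 120), c(32, 118), c(28, 122))
  base <- tube_diameter(m)
  excl <- tube_diameter(m, nuclei_centroids = cluster, exclusion_radius = 15)
  expect_equal(excl$mean_diameter_um, base$mean_diameter_um, tolerance = 0.01)
  expect_lt(excl$n_sample_sites, base$n_sample_sites)
  # a single nucleus does not trigger the cluster rule
  single <- tube_diameter(m, nuclei_centroids = cluster[1, , drop = FALSE],
                          exclusion_radius = 15)
  expect_equal(single$n_sample_sites, base$n_sample_sites)
})

test_that("diameter scales exactly with pixel size and resists rotation", {
  m <- matrix(0L, 60, 240)
  m[21:40, 21:220] <- 1L
  d1 <- tube_diameter(m, pixel_size = 1)$mean_diameter_um
  d2 <- tube_diameter(m, pixel_size = 2)$mean_diameter_um
  expect_identical(d2, 2 * d1)
  # 30-degree rotated rectangle of width 20
  g <- expand.grid(r = 1:300, c = 1:300)
  th <- 30 * pi / 180
  u <- (g$r - 150) * cos(th) + (g$c - 150) * sin(th)
  v <- -(g$r - 150) * sin(th) + (g$c - 150) * cos(th)
  rot <- matrix(0L, 300, 300)
  rot[abs(u) <= 10 & abs(v) <= 100] <- 1L
  drot <- tube_diameter(rot)$mean_diameter_um
  expect_lt(abs(drot - d1) / d1, 0.05)
})

test_that("eligibility keeps long multinucleated tubes only", {
  sl <- c(`1` = 300, `2` = 5, `3` = 250)
  nc <- c(`1` = 4L, `2` = 6L, `3` = 1L)
  expect_equal(select_measurable_tubes(sl, nc, 100, 2), 1L)
  expect_setequal(select_measurable_tubes(sl, nc, 100, 1), c(1L, 3L))
  expect_equal(select_measurable_tubes(sl, nc, 400, 2), integer(0))
})

test_that("condition summaries report mean, sample SD and n", {
  s <- condition_diameter_summary(c(10, 20))
  expect_equal(s$mean_diameter_um, 15)
  expect_equal(s$sd_diameter_um, sqrt(50), tolerance = 1e-10)
  expect_equal(condition_diameter_summary(rep(3, 5))$sd_diameter_um, 0)
  expect_error(condition_diameter_summary(17), "two tubes")
})

test_that("generator ribbon widths are recovered within five percent", {
  for (w in c(10, 17, 24)) {
    est <- vapply(1:3, function(s) {
      p <- synth_params(image_size = 448, n_nuclei = 6, n_myotubes = 1,
                        tube_width = w, tube_length = 260, true_fi = 1,
                        nucleus_radius = 3, radius_jitter = 0.5, seed = s)
      g <- generate_field(p)
      tube_diameter(g$truth$tube_labels)$mean_diameter_um
    }, numeric(1))
    expect_lt(abs(mean(est) - w) / w, 0.05)
  }
})

test_that("measure_diameters filters by length and nucleus count", {
  p <- small_params(seed = 17, n_nuclei = 16, true_fi = 0.5)
  g <- generate_field(p)
  nuc <- segment_nuclei(g$field)
  tubes <- segment_myotubes(g$field)
  cfg <- pipeline_config(min_skeleton_length = 60, diameter_min_nuclei = 2)
  res <- measure_diameters(tubes, nuc, cfg, pixel_size = g$field$pixel_size)
  expect_s3_class(res, "diameter_result")
  expect_gt(nrow(res$tubes), 0)
  expect_true(all(res$tubes$mean_diameter_um > 0))
  expect_true(all(res$tubes$nucleus_count >= 2))
  # demanding more nuclei than any tube holds excludes everything
  strict <- measure_diameters(tubes, nuc,
                              pipeline_config(min_skeleton_length = 60,
                                              diameter_min_nuclei = 50))
  expect_equal(nrow(strict$tubes), 0)
})
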