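test_that("background subtraction matches a sort-based percentile oracle", {
  # constant image: 5th percentile equals the constant, everything clamps to 0
  expect_equal(subtract_background(matrix(7, 5, 5), 5), matrix(0, 5, 5))
  # values 0..99 once each: interpolated 5th percentile is 4.95
  img <- matrix(sample(0:99), 10, 10)
  p_oracle <- {
    v <- sort(as.numeric(img))
    h <- (length(v) - 1) * 0.05
    v[floor(h) + 1] * (1 - (h - floor(h))) + v[floor(h) + 2] * (h - floor(h))
  }
  expect_equal(p_oracle, 4.95)
  expect_equal(subtract_background(img, 5), pmax(img - p_oracle, 0))
  # percentile 0 with min 0 is the identity
  expect_equal(subtract_background(img, 0), img)
  expect_error(subtract_background(img, 101), "0, 100")
})

test_that("background subtraction output is pointwise <= input and >= 0", {
  set.seed(9)
  for (i in 1:5) {
    img <- matrix(rexp(400, 1 / 50), 20, 20)
    out <- subtract_background(img, runif(1, 0, 100))
    expect_true(all(out <= img + 1e-12))
    expect_true(all(out >= 0))
  }
})

test_that("Gaussian smoothing conserves mass and fixes constants", {
  expect_equal(smooth_image(matrix(4, 15, 15), 1.2), matrix(4, 15, 15))
  imp <- matrix(0, 41, 41)
  imp[21, 21] <- 1
  expect_equal(sum(smooth_image(imp, 1.2)), 1, tolerance = 1e-3)
  expect_error(smooth_image(imp, 0), "sigma")
})

test_that("exact Otsu matches the exhaustive between-class-variance oracle", {
  set.seed(31)
  for (i in 1:25) {
    n_levels <- sample(2:256, 1)
    img <- matrix(sample(sample(0:5000, n_levels), 300, replace = TRUE),
                  15, 20)
    expect_identical(binarize(img, "otsu"), oracle_otsu_mask(img))
  }
})

test_that("Otsu on a two-valued image splits at the minority class", {
  img <- matrix(10, 20, 20)
  img[sample(400, 40)] <- 200
  t_val <- otsu_threshold(img)
  expect_gt(t_val, 10)
  expect_lt(t_val, 200)
  expect_equal(mean(binarize(img, "otsu")), 0.10)
})

test_that("degenerate and adaptive thresholding behave as documented", {
  expect_warning(m <- binarize(matrix(5, 8, 8), "otsu"), "Constant")
  expect_equal(m, matrix(0L, 8, 8))
  # constant image with positive offset: nothing exceeds local mean + offset
  expect_equal(binarize(matrix(5, 30, 30), "adaptive", adaptive_block = 5,
                        adaptive_offset = 1), matrix(0L, 30, 30))
  # bright blob on a dark background is caught by the local mean
  img <- matrix(10, 40, 40)
  img[18:23, 18:23] <- 100
  ad <- binarize(img, "adaptive", adaptive_block = 15, adaptive_offset = 5)
  expect_true(all(ad[19:22, 19:22] == 1L))
  expect_error(binarize(img, "fixed"), "arg")
})

test_that("morphological cleaning fills small holes and removes specks", {
  m <- disk_mask(31, c(16, 16), 10)
  holey <- m
  holey[15:16, 15:17] <- 0L  # 6-px interior hole
  expect_equal(clean_mask(holey, hole_max_area = 10, opening_radius = 0), m)
  # hole larger than the cap is preserved
  expect_equal(clean_mask(holey, hole_max_area = 3, opening_radius = 0), holey)
  speck <- matrix(0L, 15, 15)
  speck[8, 8] <- 1L
  expect_equal(clean_mask(speck, 0, opening_radius = 1), matrix(0L, 15, 15))
  expect_equal(clean_mask(matrix(0L, 6, 6), 10, 1), matrix(0L, 6, 6))
  expect_error(clean_mask(m, -1, 1), "nonnegative")
  # result never extends beyond the hole-filled input
  expect_true(all(clean_mask(holey, 10, 2) <= m))
})

test_that("watershed splits the analytic dumbbell into two labels", {
  # two radius-12 disks, centers 20 px apart: exactly two distance maxima
  m <- disk_mask(64, c(32, 22), 12) | disk_mask(64, c(32, 42), 12)
  m <- matrix(as.integer(m), 64, 64)
  lab <- separate_touching(m, min_distance = 7)
  expect_equal(max(lab), 2L)
  # each disk center carries a different label
  expect_true(lab[32, 22] != lab[32, 42])
  expect_true(all(lab[32, 22] > 0, lab[32, 42] > 0))
  # foreground is preserved up to watershed-line pixels
  expect_lte(sum(m) - sum(lab > 0), sum(m) * 0.02)
  expect_true(all(lab[m == 0L] == 0L))
})

test_that("watershed labels disjoint objects and empty masks correctly", {
  m <- disk_mask(80, c(20, 20), 8) + disk_mask(80, c(60, 60), 8)
  expect_equal(max(separate_touching(m, 7)), 2L)
  expect_equal(max(separate_touching(matrix(0L, 10, 10), 7)), 0L)
})

test_that("label count is non-increasing in the seed separation distance", {
  m <- disk_mask(64, c(32, 22), 12) | disk_mask(64, c(32, 42), 12)
  m <- matrix(as.integer(m), 64, 64)
  counts <- vapply(c(2, 6, 10, 16, 24), function(d)
    max(separate_touching(m, d)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("size filtering drops debris and clumps and relabels survivors", {
  lab <- matrix(0L, 40, 60)
  lab[2:3, 2:6] <- 1L               # 10 px: debris
  lab[10:19, 10:19] <- 2L           # 100 px: kept
  nl <- filter_by_size(lab, 30, 5000)
  expect_equal(nl$count, 1L)
  expect_equal(nl$areas, 100L)
  expect_equal(unname(nl$labels[15, 15]), 1L)
  big <- matrix(0L, 100, 100)
  big[10:89, 10:84] <- 1L           # 6000 px: clump
  expect_equal(filter_by_size(big, 30, 5000)$count, 0L)
  # all-within: identical object set up to labeling
  lab2 <- matrix(0L, 30, 30)
  lab2[2:9, 2:9] <- 5L
  lab2[20:27, 20:27] <- 9L
  nl2 <- filter_by_size(lab2, 30, 5000)
  expect_equal(nl2$count, 2L)
  expect_setequal(nl2$areas, c(64L, 64L))
  expect_error(filter_by_size(lab, 50, 40), "smaller")
})

test_that("the full chain recovers isolated synthetic nuclei exactly", {
  p <- synth_params(image_size = 448, n_nuclei = 40, n_myotubes = 0,
                    true_fi = 0, seed = 5)
  g <- generate_field(p)
  nl <- segment_nuclei(g$field, pipeline_config())
  expect_equal(nl$count, 40L)
  # centroid recovery: each truth center has a detected centroid within 2 px
  d <- vapply(seq_len(40), function(i) {
    min(sqrt((nl$centroids[, "row"] - g$truth$nuclei$row[i])^2 +
               (nl$centroids[, "col"] - g$truth$nuclei$col[i])^2))
  }, numeric(1))
  expect_lt(max(d), 2)
  # determinism of the whole chain
  expect_identical(segment_nuclei(g$field, pipeline_config())$labels, nl$labels)
})

test_that("a blank noisy field yields zero nuclei with a warning", {
  p <- synth_params(image_size = 256, n_nuclei = 0, n_myotubes = 0,
                    true_fi = 0, seed = 3)
  g <- generate_field(p)
  expect_warning(nl <- segment_nuclei(g$field, pipeline_config()),
                 "blank field")
  expect_equal(nl$count, 0L)
})
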