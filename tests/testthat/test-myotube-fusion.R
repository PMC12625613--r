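test_that("myotube segmentation finds ribbons and ignores blank planes", {
  cfg <- pipeline_config(myotube_min_area = 200)
  expect_warning(lab0 <- segment_myotubes(matrix(100, 64, 64), cfg),
                 "not separable")
  expect_equal(max(lab0), 0L)
  ribbon <- matrix(20, 120, 380)
  ribbon[40:69, 40:339] <- 1200  # 300 x 30 bright ribbon
  expect_equal(max(segment_myotubes(ribbon, cfg)), 1L)
})

test_that("generator ribbons are recovered with near-truth areas", {
  p <- small_params(seed = 21)
  g <- generate_field(p)
  cfg <- pipeline_config()
  lab <- segment_myotubes(g$field, cfg)
  expect_equal(max(lab), 2L)
  areas <- sort(tabulate(lab[lab > 0], nbins = 2))
  truth_areas <- sort(tabulate(g$truth$tube_labels[g$truth$tube_labels > 0],
                               nbins = 2))
  # agreement up to a boundary-halo of pixels around each ribbon
  expect_true(all(abs(areas - truth_areas) / truth_areas < 0.15))
})

test_that("nucleus-to-tube assignment follows the declared rule", {
  tubes <- matrix(0L, 20, 20)
  tubes[1:20, 11:20] <- 1L  # tube B occupies the right half
  # nucleus 60% covered by B, centroid just inside B
  lab <- matrix(0L, 20, 20)
  lab[8:12, 9:13] <- 1L     # 25 px, 15 px (60%) inside the tube
  nuc <- nuclei_labels(lab)
  ov <- count_nuclei_per_myotube(nuc, tubes, rule = "overlap",
                                 overlap_fraction = 0.5)
  expect_equal(unname(ov$counts["1"]), 1L)
  # centroid rule agrees here (centroid col 11 inside the tube)
  ce <- count_nuclei_per_myotube(nuc, tubes, rule = "centroid")
  expect_equal(ce$assignment, 1L)
  # 20% overlap with centroid outside: not counted under the centroid rule
  lab2 <- matrix(0L, 20, 20)
  lab2[8:12, 7:11] <- 1L    # only col 11 (5 of 25 px) inside
  nuc2 <- nuclei_labels(lab2)
  expect_equal(count_nuclei_per_myotube(nuc2, tubes, "centroid")$assignment, 0L)
  expect_equal(count_nuclei_per_myotube(nuc2, tubes, "overlap",
                                        overlap_fraction = 0.5)$assignment, 0L)
  expect_error(count_nuclei_per_myotube(nuc, matrix(0L, 10, 10)), "dimensions")
})

test_that("qualification applies the minimum-nuclei rule", {
  expect_equal(qualify_myotubes(c(`1` = 3L, `2` = 2L), 3), 1L)
  expect_setequal(qualify_myotubes(c(`1` = 3L, `2` = 2L), 1), c(1L, 2L))
  expect_equal(qualify_myotubes(integer(0), 3), integer(0))
  expect_error(qualify_myotubes(c(`1` = 3L), 0), ">= 1")
})

test_that("field fusion index is fused over total nuclei", {
  n <- 60
  tubes <- matrix(0L, n, n)
  tubes[20:40, 5:55] <- 1L
  lab <- matrix(0L, n, n)
  centers <- rbind(c(25, 10), c(30, 20), c(35, 30), c(28, 45),  # in tube
                   c(5, 10), c(5, 25), c(5, 40), c(50, 10), c(50, 25),
                   c(55, 45))
  for (i in seq_len(nrow(centers)))
    lab[centers[i, 1] + (-1:1), centers[i, 2] + (-1:1)] <- i
  nuc <- nuclei_labels(lab)
  r <- fusion_index_field(nuc, tubes, pipeline_config())
  expect_equal(r$total_nuclei, 10L)
  expect_equal(r$fused_nuclei, 4L)
  expect_equal(r$fi, 0.4)
  # tube not qualified: FI drops to zero
  r2 <- fusion_index_field(nuc, tubes, pipeline_config(min_nuclei_per_myotube = 5))
  expect_equal(r2$fi, 0)
  # all nuclei inside a qualified tube
  whole <- matrix(1L, n, n)
  expect_equal(fusion_index_field(nuc, whole, pipeline_config())$fi, 1)
  expect_error(fusion_index_field(nuclei_labels(matrix(0L, n, n)), tubes,
                                  pipeline_config()), "Empty field")
})

test_that("well fusion index is the unweighted field mean", {
  expect_equal(fusion_index_well(c(0.2, 0.4, 0.6, 0.8)), 0.5)
  expect_warning(v <- fusion_index_well(0.37), "convention is 4")
  expect_equal(v, 0.37)
  expect_equal(fusion_index_well(rep(0.25, 4)), 0.25)
  expect_error(fusion_index_well(numeric(0)), "at least one")
})

test_that("FI is monotone in the qualification minimum and conserves nuclei", {
  g <- generate_field(small_params(seed = 8, n_nuclei = 16, true_fi = 0.5))
  nuc <- segment_nuclei(g$field)
  tubes <- segment_myotubes(g$field)
  fis <- vapply(c(1, 2, 3, 5, 8), function(k) {
    fusion_index_field(nuc, tubes, pipeline_config(min_nuclei_per_myotube = k))$fi
  }, numeric(1))
  expect_true(all(diff(fis) <= 0))
  cn <- count_nuclei_per_myotube(nuc, tubes)
  expect_equal(sum(cn$assignment > 0) + sum(cn$assignment == 0), nuc$count)
})

test_that("centroid and overlap rules agree on fully-inside/outside truth", {
  g <- generate_field(small_params(seed = 13, n_nuclei = 18, true_fi = 0.5))
  n <- 320
  nuc <- nuclei_labels(truth_nuclei_labels(g$truth, n))
  tubes <- g$truth$tube_labels
  a <- count_nuclei_per_myotube(nuc, tubes, "centroid")$assignment
  b <- count_nuclei_per_myotube(nuc, tubes, "overlap",
                                overlap_fraction = 0.5)$assignment
  expect_identical(a, b)
  # and both recover the generator truth exactly
  fi <- fusion_index_field(nuc, tubes, pipeline_config())$fi
  expect_equal(fi, g$truth$true_fi)
})

test_that("fusion_index aggregates wells with tidy/glance accessors", {
  w <- generate_well(small_params(seed = 4, n_nuclei = 16), n_fields = 2,
                     well_id = "W7")
  expect_warning(res <- fusion_index(w$well), "convention")
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(tidy(res)), 2)
  expect_equal(glance(res)$well_id, "W7")
  expect_equal(glance(res)$fi, mean(tidy(res)$fi))
  expect_s3_class(autoplot(res), "ggplot")
})
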