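test_that("ground-truth FI is the membership ratio by construction", {
  g0 <- generate_field(small_params(seed = 2, true_fi = 0))
  expect_true(all(g0$truth$nuclei$tube == 0L))
  expect_equal(g0$truth$true_fi, 0)
  g1 <- generate_field(small_params(seed = 2, true_fi = 1, n_nuclei = 6))
  expect_true(all(g1$truth$nuclei$tube > 0L))
  expect_equal(g1$truth$true_fi, 1)
  gm <- generate_field(small_params(seed = 6, true_fi = 0.4, n_nuclei = 20))
  expect_equal(mean(gm$truth$nuclei$tube > 0), gm$truth$true_fi)
})

test_that("every populated tube holds at least the qualification minimum", {
  for (s in 1:5) {
    g <- generate_field(small_params(seed = s, true_fi = 0.45, n_nuclei = 20))
    tab <- table(g$truth$nuclei$tube[g$truth$nuclei$tube > 0])
    expect_true(all(tab >= 3))
  }
})

test_that("inside nuclei sit wholly within tubes, outside nuclei clear them", {
  g <- generate_field(small_params(seed = 11, true_fi = 0.5, n_nuclei = 16))
  lab <- truth_nuclei_labels(g$truth, 320)
  for (i in seq_len(nrow(g$truth$nuclei))) {
    tube <- g$truth$nuclei$tube[i]
    px <- g$truth$tube_labels[lab == i]
    if (tube > 0) {
      expect_true(all(px == tube))
    } else {
      expect_true(all(px == 0L))
    }
  }
})

test_that("generation is bit-identical for identical seeds", {
  p <- small_params(seed = 33)
  a <- generate_field(p)
  b <- generate_field(p)
  expect_identical(a$field$planes, b$field$planes)
  expect_identical(a$truth$nuclei, b$truth$nuclei)
  c <- generate_field(small_params(seed = 34))
  expect_false(identical(a$field$planes$nuclei, c$field$planes$nuclei))
})

test_that("wells derive distinct sub-seeds and average field truths", {
  w <- generate_well(small_params(seed = 3, true_fi = 0.4), n_fields = 4)
  expect_length(w$well$fields, 4)
  expect_equal(w$true_fi, 0.4)
  expect_false(identical(w$well$fields[[1]]$planes$nuclei,
                         w$well$fields[[2]]$planes$nuclei))
  w1 <- generate_well(small_params(seed = 3), n_fields = 1)
  expect_length(w1$well$fields, 1)
  expect_error(generate_well(small_params(seed = 3), n_fields = 0), ">= 1")
})

test_that("touching pairs are rendered at the prescribed separation", {
  p <- synth_params(image_size = 384, n_nuclei = 20, n_myotubes = 0,
                    true_fi = 0, touching_fraction = 0.5, seed = 7)
  g <- generate_field(p)
  cent <- as.matrix(g$truth$nuclei[, c("row", "col")])
  dmat <- as.matrix(dist(cent))
  diag(dmat) <- Inf
  # 5 pairs at 1.4 * mean radius = 11.2 px
  expect_equal(sum(abs(dmat - 1.4 * 8) < 1e-6) / 2, 5)
})

test_that("SDH sections have exact class counts and reproducible draws", {
  s <- generate_sdh_section(n_fibers = 100, oxidative_fraction = 0.5, seed = 1)
  expect_equal(sum(s$truth$class == "oxidative"), 50)
  s0 <- generate_sdh_section(n_fibers = 30, oxidative_fraction = 0, seed = 1)
  expect_true(all(s0$truth$class == "glycolytic"))
  s2 <- generate_sdh_section(n_fibers = 100, oxidative_fraction = 0.5, seed = 1)
  expect_identical(s$brightfield, s2$brightfield)
  expect_error(generate_sdh_section(n_fibers = 1), ">= 2")
  # oxidative fibers are darker (higher OD -> lower intensity)
  m_ox <- mean(s$truth$od[s$truth$class == "oxidative"])
  m_gl <- mean(s$truth$od[s$truth$class == "glycolytic"])
  expect_gt(m_ox, m_gl)
})

test_that("infeasible geometry is rejected rather than silently degraded", {
  expect_error(generate_field(synth_params(image_size = 256, n_myotubes = 1,
                                           tube_length = 450, true_fi = 0.5,
                                           seed = 1)),
               "Infeasible")
  expect_error(generate_field(synth_params(n_myotubes = 0, true_fi = 0.5,
                                           seed = 1)),
               "requires at least one myotube")
  expect_error(synth_params(true_fi = 1.2), "0, 1")
})

test_that("noise does not systematically bias FI recovery", {
  errs <- vapply(1:8, function(s) {
    p <- synth_params(image_size = 384, n_nuclei = 30, n_myotubes = 2,
                      tube_width = 20, tube_length = 200, true_fi = 0.4,
                      noise_sd = 45, seed = s)
    g <- generate_field(p)
    nuc <- segment_nuclei(g$field)
    tub <- segment_myotubes(g$field)
    fusion_index_field(nuc, tub)$fi - g$truth$true_fi
  }, numeric(1))
  expect_lte(abs(mean(errs)), 0.02)
})
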