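test_that("discretization captures ground-truth centerlines tightly", {
  ph <- generate_fiber_image(morphology_params("high_grade"), seed = 1)
  bp <- discretize_fibers(ph$image)
  px <- ph$image$pixel_size_um
  rows <- pmin(nrow(bp$mask), floor(ph$centerlines$y_um / px) + 1)
  cols <- pmin(ncol(bp$mask), floor(ph$centerlines$x_um / px) + 1)
  capture <- mean(bp$mask[cbind(rows, cols)])
  expect_gte(capture, 0.9)
  # mask does not balloon: stays within 3x the nominal fiber footprint
  fiber_area_um2 <- sum(!duplicated(cbind(rows, cols))) * px^2 +
    nrow(ph$fibers) * ph$params$fiber_length_um * ph$params$fiber_width_um
  expect_lte(sum(bp$mask) * px^2, 3 * fiber_area_um2)
})

test_that("constant and empty images give empty blueprints", {
  flat <- fiber_image(matrix(5, 64, 64), 0.5)
  bp <- discretize_fibers(flat)
  expect_false(any(bp$mask))
  expect_true(all(bp$graded == 0))
  dark <- fiber_image(matrix(0, 64, 64), 0.5)
  expect_false(any(discretize_fibers(dark)$mask))
})

test_that("a single straight fiber yields one component at the right angle", {
  p <- morphology_params("high_risk", n_fibers = 1L, orientation_kappa = 1e6,
                         orientation_mean_deg = 25, fiber_width_um = 1,
                         noise_model = "none", background_level = 0)
  ph <- generate_fiber_image(p, seed = 8)
  bp <- discretize_fibers(ph$image, scales_um = 0.5)
  lab <- matricell:::label_components(bp$mask)
  expect_equal(max(lab), 1L)
  idx <- which(bp$mask, arr.ind = TRUE)
  n <- nrow(idx)
  mxx <- var(idx[, 2]) * (n - 1) / n
  myy <- var(idx[, 1]) * (n - 1) / n
  mxy <- cov(idx[, 2], idx[, 1]) * (n - 1) / n
  ang <- wrap_axial(atan2(2 * mxy, mxx - myy) / 2 * 180 / pi)
  expect_lt(abs(axial_difference(ang, ph$fibers$orientation_deg)), 3)
})

test_that("discretization is invariant to global intensity rescaling", {
  ph <- generate_fiber_image(morphology_params("benign"), seed = 4)
  a <- discretize_fibers(ph$image)
  b <- discretize_fibers(fiber_image(ph$image$pixels * 7.3,
                                     ph$image$pixel_size_um))
  dice <- 2 * sum(a$mask & b$mask) / (sum(a$mask) + sum(b$mask))
  expect_gte(dice, 0.95)
})

test_that("scan plan maps grayscale to open fraction bit-exactly", {
  ph <- generate_fiber_image(morphology_params("normal"), seed = 2)
  bp <- discretize_fibers(ph$image)
  plan <- build_scan_plan(bp, dwell_us = 10, tiles = c(3L, 3L))
  expect_identical(plan$open_fraction, bp$graded)
  # 200 x 200 um pattern tiled 3 x 3 -> 600 x 600 um scaffold
  expect_equal(plan$overall_extent_um, c(600, 600))
  expect_error(build_scan_plan(bp, tiles = c(0L, 3L)), "positive")
  # all-zero graded -> no exposure anywhere
  empty <- discretize_fibers(fiber_image(matrix(1, 32, 32), 0.5))
  expect_true(all(build_scan_plan(empty)$open_fraction == 0))
})

test_that("near-delta PSF reproduces the graded map", {
  ph <- generate_fiber_image(morphology_params("high_risk"), seed = 6)
  bp <- discretize_fibers(ph$image)
  fab <- simulate_fabrication(bp, psf_fwhm_um = bp$pixel_size_um,
                              noise = "none")
  expect_lt(max(abs(fab$pixels - bp$graded)), 0.01)
})

test_that("fidelity is perfect for self and zero for the complement", {
  # graded values well separated from background so Otsu recovers the
  # support exactly
  g <- matrix(0, 80, 80)
  g[20:30, 10:70] <- 0.6
  g[50:60, 10:70] <- 1
  bp <- matricell:::new_blueprint(g > 0, g, 0.5, c(40, 40), 10)
  self <- fidelity_score(bp, fiber_image(g, 0.5))
  expect_equal(self$fidelity_pct, 100)
  expect_equal(self$spatial_overlap_pct, 100)
  expect_equal(self$intensity_corr, 1)
  comp <- fiber_image((!(g > 0)) * 1, 0.5)
  expect_equal(fidelity_score(bp, comp)$spatial_overlap_pct, 0)
})

test_that("fidelity degrades for unrelated noise and errors when empty", {
  ph <- generate_fiber_image(morphology_params("high_grade"), seed = 1)
  bp <- discretize_fibers(ph$image)
  set.seed(99)
  noise <- fiber_image(matrix(runif(length(bp$graded)), nrow(bp$graded)),
                       bp$pixel_size_um)
  expect_lt(fidelity_score(bp, noise)$fidelity_pct, 50)
  empty <- discretize_fibers(fiber_image(matrix(1, 32, 32), 0.5))
  expect_error(fidelity_score(empty, fiber_image(matrix(1, 32, 32), 0.5)),
               "empty")
})

test_that("fidelity is invariant to global rescaling of the readout", {
  ph <- generate_fiber_image(morphology_params("high_grade"), seed = 3)
  bp <- discretize_fibers(ph$image)
  fab <- simulate_fabrication(bp, seed = 5)
  a <- fidelity_score(bp, fab)
  b <- fidelity_score(bp, fiber_image(fab$pixels * 123.4, fab$pixel_size_um))
  expect_equal(a$fidelity_pct, b$fidelity_pct, tolerance = 1e-10)
})
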