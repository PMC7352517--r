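test_that("shape metrics validate their input mask", {
  expect_error(shape_metrics(matrix(FALSE, 10, 10), 1), "empty")
  two <- matrix(FALSE, 60, 60)
  two[5:25, 5:25] <- TRUE
  two[40:55, 40:55] <- TRUE
  expect_error(shape_metrics(two, 1), "2 connected components")
  small <- matrix(FALSE, 20, 20)
  small[8:12, 8:12] <- TRUE
  expect_error(shape_metrics(small, 1), "100")
})

test_that("circularity is scale and rotation invariant", {
  base <- generate_cell_mask(3, 8000, 15, 1, seed = 1)
  big <- generate_cell_mask(3, 32000, 15, 1, seed = 1)    # 2x linear scale
  rot <- generate_cell_mask(3, 8000, 125, 1, seed = 1)
  c0 <- shape_metrics(base, 1)$circularity
  expect_equal(shape_metrics(big, 1)$circularity, c0, tolerance = 0.01)
  expect_equal(shape_metrics(rot, 1)$circularity, c0, tolerance = 0.02)
})

test_that("cell-fiber alignment angle folds axially into [0, 90]", {
  m30 <- generate_cell_mask(4, 3000, 30, 1, seed = 3)
  expect_lt(cell_fiber_alignment_angle(m30, 30), 2)
  m170 <- generate_cell_mask(4, 3000, 170, 1, seed = 3)
  # cell at 170, fibers at 10: axial wrap gives 20, not 160
  expect_equal(cell_fiber_alignment_angle(m170, 10), 20, tolerance = 2)
  sm <- shape_metrics(m30, 1)
  expect_equal(cell_fiber_alignment_angle(sm, 30),
               cell_fiber_alignment_angle(m30, 30))
})

test_that("stronger guidance of cell axes lowers the mean alignment angle", {
  # emulate increasing contact guidance by drawing cell major axes with
  # increasing concentration around the fiber axis
  fiber_axis <- 40
  mean_angle <- vapply(c(0.5, 2, 8), function(k) {
    set.seed(100 + k)
    angs <- sample_axial_vonmises(40, fiber_axis, k)
    mean(vapply(seq_along(angs), function(i) {
      m <- generate_cell_mask(3, 1500, angs[i], 1, seed = i)
      cell_fiber_alignment_angle(m, fiber_axis)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_angle) < 0))
})

test_that("focal adhesion detection recovers the seeded spot field", {
  mask <- generate_cell_mask(1.5, 2000, 20, 0.25, seed = 5)
  p <- spot_field_params(n_spots = 50, spot_sigma_um = 0.4,
                         spot_amplitude = 100, cell_background = 20,
                         noise_sd = 10, cell_mask = mask)  # SNR 10
  ph <- generate_spot_image(p, seed = 7)
  det <- detect_focal_adhesions(ph$image, mask, sigma_um = 0.4)
  m <- match_spots(ph$spots, det$spots, radius_um = 2 * 0.4)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
  expect_equal(det$density_per_um2, det$count / det$cell_area_um2)
})

test_that("detection count is robust to doubling the spot amplitude", {
  mask <- generate_cell_mask(1.5, 2000, 20, 0.25, seed = 5)
  base <- spot_field_params(n_spots = 40, spot_sigma_um = 0.4,
                            spot_amplitude = 100, cell_background = 20,
                            noise_sd = 10, cell_mask = mask)
  bright <- spot_field_params(n_spots = 40, spot_sigma_um = 0.4,
                              spot_amplitude = 200, cell_background = 20,
                              noise_sd = 10, cell_mask = mask)
  d1 <- detect_focal_adhesions(generate_spot_image(base, seed = 4)$image,
                               mask, sigma_um = 0.4)
  d2 <- detect_focal_adhesions(generate_spot_image(bright, seed = 4)$image,
                               mask, sigma_um = 0.4)
  expect_equal(d1$count, d2$count, tolerance = 0.05)
})

test_that("spot density is monotone in the seeded spot count", {
  mask <- generate_cell_mask(1.5, 3000, 0, 0.25, seed = 6)
  counts <- vapply(c(10L, 40L, 80L), function(n) {
    p <- spot_field_params(n_spots = n, spot_sigma_um = 0.4,
                           spot_amplitude = 100, cell_background = 20,
                           noise_sd = 10, cell_mask = mask)
    detect_focal_adhesions(generate_spot_image(p, seed = 11)$image, mask,
                           sigma_um = 0.4)$count
  }, integer(1))
  expect_true(all(diff(counts) > 0))
})

test_that("CTCF follows its closed form and offset invariance", {
  img <- fiber_image(matrix(4, 80, 80), 1)
  cm <- matrix(FALSE, 80, 80); cm[10:30, 10:30] <- TRUE
  bm <- matrix(FALSE, 80, 80); bm[50:75, 50:75] <- TRUE
  # cell equals background -> zero
  expect_equal(ctcf(img, cm, bm)$ctcf, 0)
  # cell = background + c over area A -> c * A, exactly
  img2 <- img
  img2$pixels[cm] <- 4 + 2.5
  expect_equal(ctcf(img2, cm, bm)$ctcf, 2.5 * sum(cm))
  # adding a constant offset to the whole image changes nothing
  img3 <- fiber_image(img2$pixels + 11, 1)
  expect_equal(ctcf(img3, cm, bm)$ctcf, ctcf(img2, cm, bm)$ctcf)
  expect_error(ctcf(img, cm, cm), "disjoint")
  expect_error(ctcf(img, cm, matrix(FALSE, 80, 80)), "empty")
})

test_that("CTCF recovers injected signal against a noisy background", {
  cm <- matrix(FALSE, 120, 120); cm[11:60, 11:60] <- TRUE
  bm <- matrix(FALSE, 120, 120); bm[65:114, 65:114] <- TRUE
  injected <- 4 * sum(cm)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    px <- matrix(rpois(120^2, 50), 120, 120)
    px[cm] <- px[cm] + 4
    (ctcf(fiber_image(px, 1), cm, bm)$ctcf - injected) / injected
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.05)
})

test_that("on/off pattern expression ratio is area normalized", {
  img <- fiber_image(matrix(2, 60, 60), 1)
  on <- matrix(FALSE, 60, 60); on[5:24, 5:24] <- TRUE      # 400 px
  off <- matrix(FALSE, 60, 60); off[40:49, 40:49] <- TRUE  # 100 px
  bg <- matrix(FALSE, 60, 60); bg[52:58, 5:15] <- TRUE
  img$pixels[on] <- 2 + 6
  img$pixels[off] <- 2 + 3
  r <- ctcf_ratio(ctcf(img, on, bg), ctcf(img, off, bg))
  expect_equal(r, 2)  # per-area signal 6 vs 3 regardless of cell size
})
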