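test_that("structure tensor recovers a single fiber's orientation", {
  p <- morphology_params("high_risk", n_fibers = 1L, orientation_kappa = 1e6,
                         orientation_mean_deg = 37, noise_model = "none",
                         background_level = 0)
  ph <- generate_fiber_image(p, seed = 3)
  of <- orientation_field(ph$image, sigma_um = 2)
  on_fiber <- ph$image$pixels > 0.1 * max(ph$image$pixels)
  est <- mean_direction(as.vector(of$angle_deg),
                        as.vector(of$coherence * on_fiber))
  expect_lt(abs(axial_difference(est, ph$fibers$orientation_deg)), 2)
})

test_that("orientation field is equivariant under 90-degree rotation", {
  p <- morphology_params("high_risk", n_fibers = 1L, orientation_kappa = 1e6,
                         orientation_mean_deg = 37, noise_model = "none",
                         background_level = 0)
  ph <- generate_fiber_image(p, seed = 3)
  m <- ph$image$pixels
  rot <- t(m)[ncol(m):1, ]  # rotate the raster by 90 degrees
  of1 <- orientation_field(ph$image, sigma_um = 2)
  of2 <- orientation_field(fiber_image(rot, 0.5), sigma_um = 2)
  on1 <- m > 0.1 * max(m)
  on2 <- rot > 0.1 * max(rot)
  a1 <- mean_direction(as.vector(of1$angle_deg),
                       as.vector(of1$coherence * on1))
  a2 <- mean_direction(as.vector(of2$angle_deg),
                       as.vector(of2$coherence * on2))
  expect_lt(abs(axial_difference(wrap_axial(a1 + 90), a2)), 2)
})

test_that("flat and isotropic images carry no orientation signal", {
  flat <- fiber_image(matrix(3, 64, 64), 1)
  of <- orientation_field(flat, sigma_um = 2)
  expect_true(of$flat)
  expect_true(all(of$coherence == 0))
  expect_true(all(of$angle_deg == 0))
  set.seed(5)
  noise <- fiber_image(matrix(rpois(400 * 400, 100), 400, 400), 0.5)
  ofn <- orientation_field(noise, sigma_um = 2)
  expect_lt(mean(ofn$coherence), 0.2)
})

test_that("angular distributions are normalized and well behaved", {
  d <- angular_distribution(rep(45, 100), n_bins = 36L)
  expect_equal(sum(d$density), 1)
  expect_equal(max(d$density), 1)  # single occupied bin
  expect_equal(tidy(d)$bin_mid_deg[which.max(d$density)], 47.5)
  expect_error(angular_distribution(runif(10, 0, 180), n_bins = 4L), "8")
  # near-uniform sample: no bin wildly over-occupied
  set.seed(8)
  u <- angular_distribution(runif(2e4, 0, 180), n_bins = 36L)
  expect_lte(max(u$density), 3 / 36)
})

test_that("alignment index matches the Bessel-ratio closed form", {
  expect_equal(alignment_index(angular_distribution(rep(45, 50), 36L)), 1,
               tolerance = 0.01)
  uni <- angular_distribution(seq(2.5, 177.5, by = 5), n_bins = 36L)
  expect_equal(alignment_index(uni), 0, tolerance = 1e-10)
  set.seed(12)
  vm <- angular_distribution(sample_axial_vonmises(2e4, 30, 4), n_bins = 36L)
  A4 <- besselI(4, 1) / besselI(4, 0)
  expect_equal(alignment_index(vm), A4, tolerance = 0.05)
})

test_that("aligned phantoms have higher alignment index than random ones", {
  ph_hg <- generate_fiber_image(morphology_params("high_grade"), seed = 2)
  ph_n <- generate_fiber_image(morphology_params("normal"), seed = 2)
  ai <- function(ph) {
    of <- orientation_field(ph$image, sigma_um = 2)
    alignment_index(angular_distribution(of, 36L, weight = "coherence"))
  }
  expect_gt(ai(ph_hg), ai(ph_n))
})

test_that("pearson_between behaves on identical, symmetric, and null data", {
  set.seed(3)
  a <- angular_distribution(sample_axial_vonmises(500, 60, 3), 36L)
  expect_equal(pearson_between(a, a), 1)
  b <- angular_distribution(sample_axial_vonmises(500, 60, 3), 24L)
  expect_error(pearson_between(a, b), "bin edges")
  # independent uniform samples decorrelate: the null correlation between
  # two k-bin histograms has sd ~ 1/sqrt(k - 1) (~0.17 at 36 bins)
  # regardless of sample size, so the check is against that law
  rs <- replicate(200, {
    da <- angular_distribution(runif(1e4, 0, 180), 36L)
    db <- angular_distribution(runif(1e4, 0, 180), 36L)
    pearson_between(da, db)
  })
  expect_lt(abs(mean(rs)), 0.05)
  expect_lt(sd(rs), 2 / sqrt(35))
  expect_gte(mean(abs(rs) < 0.5), 0.95)
})

test_that("guided trajectories correlate with the fiber distribution", {
  # qualitative analogue of relating stress-fiber and collagen histograms:
  # headings under strong contact guidance along 60 deg correlate with a
  # fiber distribution aligned at 60 deg more than unguided headings do
  set.seed(6)
  fibers <- angular_distribution(sample_axial_vonmises(2000, 60, 8), 36L)
  p_guided <- prw_params(n_cells = 150L, n_frames = 40L,
                         guidance_strength = 0.6, guidance_axis_deg = 60)
  p_free <- prw_params(n_cells = 150L, n_frames = 40L)
  hg <- step_directions(generate_trajectories(p_guided, seed = 13))
  hf <- step_directions(generate_trajectories(p_free, seed = 13))
  r_guided <- pearson_between(angular_distribution(hg$axial_deg, 36L), fibers)
  r_free <- pearson_between(angular_distribution(hf$axial_deg, 36L), fibers)
  expect_gt(r_guided, r_free)
})

test_that("watson_u2 separates shifted laws and accepts identical ones", {
  set.seed(10)
  a <- sample_axial_vonmises(50, 0, 4)
  b <- sample_axial_vonmises(50, 90, 4)
  res <- watson_u2(a, b, n_permutations = 499, seed = 1)
  expect_lt(res$p_value, 0.01)
  same <- watson_u2(a, a, n_permutations = 499, seed = 1)
  expect_gt(same$p_value, 0.9)
  expect_lt(same$u2, res$u2)
  expect_error(watson_u2(a[1:5], b, 99), "at least 8")
})

test_that("watson_u2 is invariant under common rotation of both samples", {
  set.seed(14)
  a <- sample_axial_vonmises(40, 20, 2)
  b <- sample_axial_vonmises(40, 70, 2)
  r1 <- watson_u2(a, b, n_permutations = 199, seed = 5)
  r2 <- watson_u2(wrap_axial(a + 57), wrap_axial(b + 57),
                  n_permutations = 199, seed = 5)
  expect_equal(r1$u2, r2$u2, tolerance = 1e-12)
})

test_that("watson_u2 has power against axis-rotated alternatives", {
  set.seed(20)
  rej <- replicate(100, {
    a <- sample_axial_vonmises(50, 0, 4)
    b <- sample_axial_vonmises(50, 90, 4)
    watson_u2(a, b, n_permutations = 199)$p_value < 0.05
  })
  expect_gt(mean(rej), 0.9)
})
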