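make_track <- function(x, y, dt = 30, id = 1L) {
  tibble::tibble(track_id = id, t_min = (seq_along(x) - 1) * dt,
                 x_um = x, y_um = y)
}

test_that("instantaneous speeds follow the displacement arithmetic", {
  # straight line, 10 um per 30-min step -> 1/3 um/min
  tr <- make_track(x = seq(0, 100, by = 10), y = rep(0, 11))
  sp <- instantaneous_speeds(tr)
  expect_equal(sp$speed_um_per_min, rep(1 / 3, 10))
  still <- make_track(x = rep(2, 8), y = rep(5, 8))
  expect_true(all(instantaneous_speeds(still)$speed_um_per_min == 0))
})

test_that("speeds agree with a brute-force reimplementation", {
  tr <- generate_trajectories(prw_params(n_cells = 15L, n_frames = 20L),
                              seed = 2)
  fast <- instantaneous_speeds(tr)$speed_um_per_min
  slow <- brute_force_speeds(tr)
  expect_equal(sort(fast), sort(slow))
})

test_that("step directions use the image convention (y down)", {
  right <- make_track(x = 0:5, y = rep(0, 6))
  expect_true(all(step_directions(right)$heading_deg == 0))
  up <- make_track(x = rep(0, 6), y = seq(0, -50, by = -10))
  expect_true(all(step_directions(up)$heading_deg == 270))
})

test_that("time-averaged MSD is exact for ballistic motion", {
  s <- 0.5  # um/min
  tr <- make_track(x = s * 30 * (0:30), y = rep(0, 31))
  curve <- suppressMessages(ensemble_msd(tr))
  expect_equal(curve$msd_um2, s^2 * curve$lag_min^2)
  expect_true(all(diff(curve$n_pairs) < 0))
  # duplicating a track does not change the ensemble curve
  two <- dplyr::bind_rows(tr, dplyr::mutate(tr, track_id = 2L))
  expect_equal(suppressMessages(ensemble_msd(two))$msd_um2, curve$msd_um2)
})

test_that("short tracks are excluded and empty ensembles error", {
  long <- make_track(x = rnorm(20), y = rnorm(20), id = 1L)
  short <- make_track(x = rnorm(4), y = rnorm(4), id = 2L)
  expect_message(ensemble_msd(dplyr::bind_rows(long, short)), "excluded")
  expect_error(suppressMessages(ensemble_msd(short)), "long enough")
})

test_that("fitting the model to its own curve is exact", {
  lags <- seq(30, 1440, by = 30)
  curve <- tibble::tibble(lag_min = lags,
                          msd_um2 = furth_msd(lags, mu = 10, P = 30))
  fit <- fit_prw(curve)
  expect_true(fit$converged)
  expect_true(fit$identifiable_P)
  expect_equal(fit$mu_um2_per_min, 10, tolerance = 1e-3)
  expect_equal(fit$P_min, 30, tolerance = 1e-3)
})

test_that("ballistic curves flag P as unidentifiable", {
  lags <- seq(30, 1440, by = 30)
  fit <- fit_prw(tibble::tibble(lag_min = lags, msd_um2 = 0.25 * lags^2))
  expect_true(fit$converged)
  expect_false(fit$identifiable_P)
  expect_error(fit_prw(tibble::tibble(lag_min = 1:3, msd_um2 = 1:3)),
               "4 lags")
})

test_that("speeds, MSD and fits are invariant under rigid motions", {
  tr <- generate_trajectories(prw_params(n_cells = 30L, n_frames = 40L),
                              seed = 5)
  th <- pi / 5
  moved <- dplyr::mutate(tr,
    xr = cos(th) * x_um - sin(th) * y_um + 123,
    yr = sin(th) * x_um + cos(th) * y_um - 45,
    x_um = xr, y_um = yr
  )[c("track_id", "t_min", "x_um", "y_um")]
  expect_equal(instantaneous_speeds(moved)$speed_um_per_min,
               instantaneous_speeds(tr)$speed_um_per_min)
  ca <- ensemble_msd(tr)
  cb <- ensemble_msd(moved)
  expect_equal(cb$msd_um2, ca$msd_um2)
  fa <- fit_prw(ca)
  fb <- fit_prw(cb)
  expect_equal(fb$mu_um2_per_min, fa$mu_um2_per_min, tolerance = 1e-8)
  expect_equal(fb$P_min, fa$P_min, tolerance = 1e-8)
})

test_that("motility estimates are consistent across sampling intervals", {
  a <- generate_trajectories(prw_params(dt_min = 30, n_frames = 145L,
                                        n_cells = 200L), seed = 17)
  b <- generate_trajectories(prw_params(dt_min = 60, n_frames = 73L,
                                        n_cells = 200L), seed = 18)
  fa <- fit_prw(ensemble_msd(a))
  fb <- fit_prw(ensemble_msd(b))
  expect_equal(fa$mu_um2_per_min, fb$mu_um2_per_min, tolerance = 0.2)
})

test_that("per-cell fitting mode returns per-track estimates", {
  tr <- generate_trajectories(prw_params(n_cells = 10L, n_frames = 60L),
                              seed = 9)
  res <- fit_motility(tr, mode = "per_cell")
  expect_equal(nrow(res$fits), 10L)
  expect_true(is.finite(res$median_mu))
  # per-cell medians agree with the ensemble fit at coarse tolerance
  ens <- fit_motility(tr, mode = "ensemble")
  expect_equal(res$median_mu, ens$mu_um2_per_min, tolerance = 0.75)
})

test_that("irregular sampling is flagged", {
  tr <- tibble::tibble(track_id = 1L, t_min = c(0, 30, 61, 90, 120, 150,
                                                180, 210, 240, 270, 300),
                       x_um = rnorm(11), y_um = rnorm(11))
  expect_warning(instantaneous_speeds(tr), "irregular")
})
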