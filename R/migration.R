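#' Trajectory table checks
#'
#' Trajectory tables have one row per cell and time point with columns
#' `track_id`, `t_min`, `x_um`, `y_um` (a 0-based `frame` column is
#' accepted and ignored). Sampling must be uniform per track within 1%;
#' tracks with irregular gaps are flagged with a warning.
#'
#' @keywords internal
#' @noRd
check_trajectories <- function(tracks) {
  need <- c("track_id", "t_min", "x_um", "y_um")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) {
    stop("trajectory table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- tracks |>
    dplyr::arrange(.data$track_id, .data$t_min) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      irregular = dplyr::n() > 2 &&
        (max(diff(.data$t_min)) - min(diff(.data$t_min))) >
          0.01 * stats::median(diff(.data$t_min)),
      .groups = "drop"
    )
  if (any(bad$n < 2)) stop("every track needs at least 2 samples", call. = FALSE)
  if (any(bad$irregular)) {
    warning(sum(bad$irregular), " track(s) have irregular sampling intervals",
            call. = FALSE)
  }
  invisible(tracks)
}

#' Instantaneous migration speeds
#'
#' Speed of each step: Euclidean displacement between consecutive samples
#' divided by the time interval.
#'
#' @param tracks Trajectory tibble (`track_id`, `t_min`, `x_um`, `y_um`).
#' @return Tibble with `track_id`, `t_min` (end of step), `speed_um_per_min`.
#' @export
#' @examples
#' tr <- generate_trajectories(prw_params(n_cells = 3, n_frames = 10), seed = 1)
#' instantaneous_speeds(tr) |> head()
instantaneous_speeds <- function(tracks) {
  check_trajectories(tracks)
  tracks |>
    dplyr::arrange(.data$track_id, .data$t_min) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(
      speed_um_per_min = sqrt(
        (.data$x_um - dplyr::lag(.data$x_um))^2 +
        (.data$y_um - dplyr::lag(.data$y_um))^2
      ) / (.data$t_min - dplyr::lag(.data$t_min))
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$speed_um_per_min)) |>
    dplyr::select("track_id", "t_min", "speed_um_per_min")
}

#' Step heading directions
#'
#' Heading of each step in degrees, measured from +x with y pointing down
#' (image convention): a step in -y is 270. The axial projection
#' (`heading_deg` mod 180) is included for comparison with fiber
#' orientation distributions.
#'
#' @inheritParams instantaneous_speeds
#' @return Tibble with `track_id`, `t_min`, `heading_deg` in `[0, 360)`,
#'   `axial_deg` in `[0, 180)`.
#' @export
step_directions <- function(tracks) {
  check_trajectories(tracks)
  tracks |>
    dplyr::arrange(.data$track_id, .data$t_min) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(
      dx = .data$x_um - dplyr::lag(.data$x_um),
      dy = .data$y_um - dplyr::lag(.data$y_um),
      heading_deg = (atan2(.data$dy, .data$dx) * 180 / pi) %% 360
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$heading_deg)) |>
    dplyr::mutate(axial_deg = .data$heading_deg %% 180) |>
    dplyr::select("track_id", "t_min", "heading_deg", "axial_deg")
}

#' Ensemble mean squared displacement
#'
#' Per-track time-averaged MSD over all overlapping pairs at each lag,
#' then a pair-count-weighted ensemble average across tracks. Lags are
#' restricted to at most `max_lag_fraction` of the track duration (default
#' 1/3), the standard guard against the high-variance tail of time-averaged
#' MSD curves. Tracks shorter than `min_track_frames` samples are excluded
#' with a message.
#'
#' @inheritParams instantaneous_speeds
#' @param max_lag_fraction Fraction of track duration to retain (0, 1].
#' @param min_track_frames Minimum samples for a track to enter the
#'   ensemble (default 10).
#' @return A tibble of class `msd_curve` with columns `lag_min`,
#'   `msd_um2`, `n_pairs`, and attributes `n_tracks`, `dt_min`.
#' @export
#' @examples
#' tr <- generate_trajectories(prw_params(n_cells = 20, n_frames = 30), seed = 1)
#' ensemble_msd(tr)
ensemble_msd <- function(tracks, max_lag_fraction = 1 / 3,
                         min_track_frames = 10L) {
  stopifnot(max_lag_fraction > 0, max_lag_fraction <= 1)
  check_trajectories(tracks)
  split_tracks <- split(tracks[c("t_min", "x_um", "y_um")], tracks$track_id)
  lens <- vapply(split_tracks, nrow, integer(1))
  short <- lens < max(3L, min_track_frames)
  if (all(short)) stop("no track long enough for an MSD curve", call. = FALSE)
  if (any(short)) {
    message(sum(short), " track(s) shorter than ", min_track_frames,
            " frames excluded from the MSD ensemble")
    split_tracks <- split_tracks[!short]
  }
  acc <- list()
  for (tr in split_tracks) {
    tr <- tr[order(tr$t_min), ]
    n <- nrow(tr)
    dt <- stats::median(diff(tr$t_min))
    max_lag <- max(1L, floor((n - 1L) * max_lag_fraction))
    lag_idx <- seq_len(max_lag)
    sums <- numeric(max_lag)
    for (L in lag_idx) {
      d2 <- (tr$x_um[(1 + L):n] - tr$x_um[1:(n - L)])^2 +
            (tr$y_um[(1 + L):n] - tr$y_um[1:(n - L)])^2
      sums[L] <- sum(d2)
    }
    acc[[length(acc) + 1L]] <- tibble::tibble(
      lag_min = lag_idx * dt,
      sum_d2 = sums,
      n_pairs = n - lag_idx
    )
  }
  out <- dplyr::bind_rows(acc) |>
    dplyr::group_by(.data$lag_min) |>
    dplyr::summarise(
      msd_um2 = sum(.data$sum_d2) / sum(.data$n_pairs),
      n_pairs = sum(.data$n_pairs),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$lag_min)
  attr(out, "n_tracks") <- length(split_tracks)
  attr(out, "dt_min") <- stats::median(diff(sort(unique(out$lag_min))))
  class(out) <- c("msd_curve", class(out))
  out
}

#' Fit the persistent-random-walk MSD model
#'
#' Nonlinear least squares of the Furth formula
#' \eqn{\langle d^2(t)\rangle = 2 n_d \mu [t - P(1 - e^{-t/P})]}
#' over motility coefficient `mu` and persistence time `P`, both constrained
#' positive. Initialization: `mu0` from the slope of the last half of the
#' curve divided by `2 n_d` (the diffusive limit), `P0` at the first lag.
#' `identifiable_P` is set `FALSE` when the fitted `P` sits within 1% of its
#' bound, exceeds the largest observed lag (the curve never leaves the
#' ballistic regime inside the window), or has a standard error exceeding
#' the estimate — all symptoms of near-ballistic data where only the ratio
#' `mu / P` is determined.
#'
#' @param curve An [ensemble_msd()] result (or tibble with `lag_min`,
#'   `msd_um2`, optionally `n_pairs`), with at least 4 lags.
#' @param n_d Dimensionality (default 2).
#' @param weight_by_pairs If `TRUE`, weight residuals by `n_pairs`
#'   (off by default: plain least squares on the retained lags).
#' @return An object of class `prw_fit`: list with `mu_um2_per_min`,
#'   `P_min`, `n_d`, `rss`, `converged`, `identifiable_P`, `stderr_mu`,
#'   `stderr_P`, `n_lags`, and the fitted curve.
#' @export
#' @examples
#' lags <- seq(30, 1440, by = 30)
#' curve <- tibble::tibble(lag_min = lags, msd_um2 = prw_msd(lags, 10, 30))
#' fit_prw(curve)
fit_prw <- function(curve, n_d = 2L, weight_by_pairs = FALSE) {
  stopifnot(all(c("lag_min", "msd_um2") %in% names(curve)))
  lag <- curve$lag_min
  msd <- curve$msd_um2
  if (length(lag) < 4) stop("need at least 4 lags to fit", call. = FALSE)
  w <- if (weight_by_pairs && "n_pairs" %in% names(curve)) curve$n_pairs
       else rep(1, length(lag))

  half <- lag >= stats::median(lag)
  slope <- stats::coef(stats::lm(msd[half] ~ lag[half]))[2]
  mu0 <- max(slope / (2 * n_d), 1e-8)
  P0 <- lag[1]
  P_upper <- 1e3 * max(lag)

  fits <- list()
  starts <- list(c(mu = mu0, P = P0),
                 c(mu = mu0, P = max(lag) / 2),
                 c(mu = mu0 * 10, P = P0))
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        msd ~ 2 * n_d * mu * (lag - P * (1 - exp(-lag / P))),
        start = list(mu = st[["mu"]], P = st[["P"]]),
        lower = c(mu = 1e-12, P = 1e-6),
        upper = c(mu = Inf, P = P_upper),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) {
    return(structure(list(
      mu_um2_per_min = NA_real_, P_min = NA_real_, n_d = as.integer(n_d),
      rss = NA_real_, converged = FALSE, identifiable_P = FALSE,
      stderr_mu = NA_real_, stderr_P = NA_real_, n_lags = length(lag),
      curve = curve
    ), class = "prw_fit"))
  }
  rss_all <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  fit <- fits[[which.min(rss_all)]]
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(mu = NA_real_, P = NA_real_))
  P_hat <- unname(co[["P"]])
  identifiable <- !(P_hat > 0.99 * P_upper || P_hat < 1.01e-6 ||
                    P_hat > max(lag) ||
                    !is.finite(se[["P"]]) || se[["P"]] / P_hat > 1)
  structure(list(
    mu_um2_per_min = unname(co[["mu"]]),
    P_min = P_hat,
    n_d = as.integer(n_d),
    rss = sum(stats::resid(fit)^2),
    converged = TRUE,
    identifiable_P = identifiable,
    stderr_mu = unname(se[["mu"]]),
    stderr_P = unname(se[["P"]]),
    n_lags = length(lag),
    curve = curve
  ), class = "prw_fit")
}

#' @export
print.prw_fit <- function(x, ...) {
  cat(sprintf(
    "PRW fit: mu = %.4g um^2/min, P = %.4g min (n_d = %d, %d lags, rss = %.4g)%s\n",
    x$mu_um2_per_min, x$P_min, x$n_d, x$n_lags, x$rss,
    if (!x$identifiable_P) " [P not identifiable]" else ""
  ))
  invisible(x)
}

#' Fit motility from a trajectory table
#'
#' Convenience wrapper: computes the ensemble MSD and fits the PRW model.
#' `mode = "ensemble"` (default) fits one model to the pooled curve;
#' `mode = "per_cell"` fits each track's time-averaged MSD separately and
#' also reports the median of the per-cell estimates.
#'
#' @inheritParams ensemble_msd
#' @inheritParams fit_prw
#' @param mode `"ensemble"` or `"per_cell"`.
#' @return For `"ensemble"`, a `prw_fit`. For `"per_cell"`, a list with
#'   `fits` (tibble of per-track estimates) and `median_mu`, `median_P`.
#' @export
fit_motility <- function(tracks, mode = c("ensemble", "per_cell"),
                         max_lag_fraction = 1 / 3, n_d = 2L,
                         min_track_frames = 10L) {
  mode <- match.arg(mode)
  if (mode == "ensemble") {
    return(fit_prw(ensemble_msd(tracks, max_lag_fraction, min_track_frames),
                   n_d = n_d))
  }
  per <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(df, key) {
      df$track_id <- key$track_id
      curve <- tryCatch(
        suppressMessages(ensemble_msd(df, max_lag_fraction, min_track_frames)),
        error = function(e) NULL
      )
      if (is.null(curve) || nrow(curve) < 4) return(NULL)
      f <- fit_prw(curve, n_d = n_d)
      tibble::tibble(track_id = key$track_id, mu_um2_per_min = f$mu_um2_per_min,
                     P_min = f$P_min, converged = f$converged,
                     identifiable_P = f$identifiable_P)
    }) |>
    dplyr::bind_rows()
  list(
    fits = per,
    median_mu = stats::median(per$mu_um2_per_min, na.rm = TRUE),
    median_P = stats::median(per$P_min, na.rm = TRUE)
  )
}
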