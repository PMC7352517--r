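#' Parameters for the persistent-random-walk trajectory generator
#'
#' The persistent random walk (PRW) models cell velocity as a stationary
#' Ornstein--Uhlenbeck process: speed fluctuations decorrelate exponentially
#' with persistence time `P_min`, and long-time motion is diffusive with
#' motility coefficient `mu_um2_per_min`. Its ensemble mean squared
#' displacement is the Furth formula
#' \deqn{\langle d^2(t)\rangle = 2 n_d \mu \left[t - P(1 - e^{-t/P})\right]}
#' with dimensionality `n_d = 2` for cells migrating on a scaffold surface.
#'
#' Defaults mirror a 72-hour time-lapse experiment sampled every 30 minutes
#' (145 frames including frame 0).
#'
#' @param mu_um2_per_min Motility coefficient in um^2/min (> 0).
#' @param P_min Directional persistence time in minutes (> 0).
#' @param dt_min Sampling interval in minutes (> 0).
#' @param n_frames Number of sampled frames per cell (>= 2).
#' @param n_cells Number of cells (>= 1).
#' @param guidance_strength Non-negative contact-guidance bias; 0 gives the
#'   pure PRW for which the Furth formula holds exactly.
#' @param guidance_axis_deg Fiber axis (degrees, axial) used when no
#'   orientation field is supplied and `guidance_strength > 0`.
#' @param n_d Dimensionality; fixed at 2.
#' @return A list of class `prw_params`.
#' @export
prw_params <- function(mu_um2_per_min = 10, P_min = 30, dt_min = 30,
                       n_frames = 145L, n_cells = 500L,
                       guidance_strength = 0, guidance_axis_deg = NA_real_,
                       n_d = 2L) {
  stopifnot(mu_um2_per_min > 0, P_min > 0, dt_min > 0, n_frames >= 2,
            n_cells >= 1, guidance_strength >= 0, n_d == 2L)
  structure(list(
    mu_um2_per_min = mu_um2_per_min, P_min = P_min, dt_min = dt_min,
    n_frames = as.integer(n_frames), n_cells = as.integer(n_cells),
    guidance_strength = guidance_strength,
    guidance_axis_deg = guidance_axis_deg, n_d = 2L
  ), class = "prw_params")
}

#' Furth mean squared displacement of the persistent random walk
#'
#' Closed-form ensemble MSD \eqn{2 n_d \mu [t - P(1 - e^{-t/P})]}.
#'
#' @param t_min Lag times in minutes.
#' @param mu_um2_per_min Motility coefficient (um^2/min).
#' @param P_min Persistence time (min).
#' @param n_d Dimensionality (default 2).
#' @return MSD in um^2 at each lag.
#' @export
#' @examples
#' prw_msd(c(30, 60, 120), mu_um2_per_min = 10, P_min = 30)
prw_msd <- function(t_min, mu_um2_per_min, P_min, n_d = 2) {
  2 * n_d * mu_um2_per_min * (t_min - P_min * (1 - exp(-t_min / P_min)))
}

#' Simulate seeded persistent-random-walk cell trajectories
#'
#' Velocities follow a stationary zero-mean Ornstein--Uhlenbeck process with
#' per-component variance `mu / P` and correlation time `P`; positions are
#' the time integral. Integration uses the exact OU velocity update at
#' substeps of `dt / 50` (decay `exp(-delta/P)`, innovation variance
#' `(mu/P) * (1 - exp(-2*delta/P))` per component) with trapezoidal position
#' integration, and the initial velocity is drawn from the stationary law so
#' the process is stationary from frame 0. With `guidance_strength > 0` a
#' contact-guidance bias is applied (under which the Furth formula no
#' longer holds): at each sampled step the velocity is rotated toward the
#' local fiber axis by `guidance_strength` times the axial angular
#' difference (capped at the difference), and the velocity component along
#' the axis is given a longer persistence time and proportionally larger
#' stationary variance (`P_par = P * (1 + g)`, `var_par = mu / P * (1 + g)`)
#' while the perpendicular component is untouched. Together these align
#' headings with the fibers and raise long-time motility, the qualitative
#' signature of contact-guided migration on aligned matrices.
#'
#' @param params A [prw_params()] object.
#' @param seed Integer seed.
#' @param orientation_field Optional [orientation_field] giving the local
#'   fiber axis for contact guidance; required if `guidance_strength > 0`
#'   and `guidance_axis_deg` is `NA`.
#' @return A tibble with columns `track_id`, `frame` (0-based), `t_min`,
#'   `x_um`, `y_um`, one row per cell and frame.
#' @export
#' @examples
#' tr <- generate_trajectories(prw_params(n_cells = 5, n_frames = 10), seed = 1)
#' head(tr)
generate_trajectories <- function(params, seed, orientation_field = NULL) {
  stopifnot(inherits(params, "prw_params"))
  guided <- params$guidance_strength > 0
  if (guided && is.null(orientation_field) && is.na(params$guidance_axis_deg)) {
    stop("guidance_strength > 0 requires an orientation_field or guidance_axis_deg",
         call. = FALSE)
  }
  withr::local_seed(as.integer(seed))

  n <- params$n_cells
  nf <- params$n_frames
  dt <- params$dt_min
  P <- params$P_min
  mu <- params$mu_um2_per_min
  n_sub <- 50L
  delta <- dt / n_sub
  decay <- exp(-delta / P)
  innov_sd <- sqrt((mu / P) * (1 - decay^2))
  stat_sd <- sqrt(mu / P)

  # start positions: inside the field extent if one is given, else origin
  if (!is.null(orientation_field)) {
    ext <- dim(orientation_field$angle_deg) * orientation_field$pixel_size_um
    x <- stats::runif(n, 0, ext[2])
    y <- stats::runif(n, 0, ext[1])
  } else {
    x <- numeric(n)
    y <- numeric(n)
  }
  vx <- stats::rnorm(n, sd = stat_sd)
  vy <- stats::rnorm(n, sd = stat_sd)

  X <- matrix(NA_real_, n, nf)
  Y <- matrix(NA_real_, n, nf)
  X[, 1] <- x
  Y[, 1] <- y

  g <- params$guidance_strength
  if (guided) {
    P_par <- P * (1 + g)
    decay_par <- exp(-delta / P_par)
    innov_par_sd <- sqrt((mu / P) * (1 + g) * (1 - decay_par^2))
  }

  for (f in 2:nf) {
    if (guided) {
      axis_deg <- local_fiber_axis(orientation_field, x, y,
                                   params$guidance_axis_deg)
      heading <- rad2deg(atan2(vy, vx))
      d <- axial_difference(heading, axis_deg)
      rot <- deg2rad(sign(d) * pmin(g * abs(d), abs(d)))
      cs <- cos(rot); sn <- sin(rot)
      vx2 <- cs * vx - sn * vy
      vy2 <- sn * vx + cs * vy
      vx <- vx2; vy <- vy2
      # anisotropic OU in the fiber frame: persistent along the axis
      th <- deg2rad(axis_deg)
      ct <- cos(th); st <- sin(th)
      for (s in seq_len(n_sub)) {
        vpar <- ct * vx + st * vy
        vperp <- -st * vx + ct * vy
        nvpar <- decay_par * vpar + stats::rnorm(n, sd = innov_par_sd)
        nvperp <- decay * vperp + stats::rnorm(n, sd = innov_sd)
        nvx <- ct * nvpar - st * nvperp
        nvy <- st * nvpar + ct * nvperp
        x <- x + delta * (vx + nvx) / 2
        y <- y + delta * (vy + nvy) / 2
        vx <- nvx; vy <- nvy
      }
    } else {
      for (s in seq_len(n_sub)) {
        nvx <- decay * vx + stats::rnorm(n, sd = innov_sd)
        nvy <- decay * vy + stats::rnorm(n, sd = innov_sd)
        x <- x + delta * (vx + nvx) / 2
        y <- y + delta * (vy + nvy) / 2
        vx <- nvx; vy <- nvy
      }
    }
    X[, f] <- x
    Y[, f] <- y
  }

  tibble::tibble(
    track_id = rep(seq_len(n), each = nf),
    frame = rep(0:(nf - 1L), times = n),
    t_min = rep((0:(nf - 1L)) * dt, times = n),
    x_um = as.vector(t(X)),
    y_um = as.vector(t(Y))
  )
}

# fiber axis (degrees, axial) at positions (x, y) in um; constant axis if no
# field is supplied, nearest-pixel lookup (clamped to the field) otherwise.
local_fiber_axis <- function(field, x_um, y_um, fallback_axis_deg) {
  if (is.null(field)) {
    return(rep(fallback_axis_deg, length(x_um)))
  }
  px <- field$pixel_size_um
  d <- dim(field$angle_deg)
  rows <- pmin(d[1], pmax(1L, as.integer(floor(y_um / px)) + 1L))
  cols <- pmin(d[2], pmax(1L, as.integer(floor(x_um / px)) + 1L))
  field$angle_deg[cbind(rows, cols)]
}
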