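#' Angular utilities for axial (orientation) data
#'
#' Fiber and stress-fiber orientations are axial: an angle and its opposite
#' describe the same axis, so all orientation statistics here work modulo
#' 180 degrees by doubling angles, applying ordinary circular statistics,
#' and halving back.
#'
#' @name angles
#' @keywords internal
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into the axial range [0, 180)
#'
#' @param angle_deg Numeric vector of angles in degrees.
#' @return Angles wrapped modulo 180, in `[0, 180)`.
#' @export
#' @examples
#' wrap_axial(c(-10, 190, 45))
wrap_axial <- function(angle_deg) {
  angle_deg %% 180
}

#' Signed axial difference between two orientations
#'
#' Smallest signed rotation (degrees, in `(-90, 90]`) taking axis `from`
#' onto axis `to`.
#'
#' @param from,to Angles in degrees (axial, mod 180).
#' @return Signed difference in degrees.
#' @export
axial_difference <- function(from, to) {
  d <- (to - from) %% 180
  ifelse(d > 90, d - 180, d)
}

#' Mean resultant length of axial angles
#'
#' Order parameter of a set of orientations: 1 for perfectly aligned axes,
#' ~0 for isotropic ones. Computed on doubled angles.
#'
#' @param angle_deg Angles in degrees (axial).
#' @param w Optional non-negative weights.
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' axial_order_parameter(c(30, 30, 30))   # 1
#' axial_order_parameter(c(0, 90))        # 0
axial_order_parameter <- function(angle_deg, w = NULL) {
  if (length(angle_deg) == 0L) return(NA_real_)
  th <- deg2rad(2 * angle_deg)
  if (is.null(w)) w <- rep(1, length(th))
  stopifnot(all(w >= 0), length(w) == length(th))
  sw <- sum(w)
  if (sw == 0) return(NA_real_)
  Mod(sum(w * exp(1i * th)) / sw)
}

#' Mean direction of axial angles
#'
#' Half of the circular mean of doubled angles, so that e.g. 10 and 170
#' degrees average to 0 (the two axes straddle the 0/180 wrap), not 90.
#'
#' @inheritParams axial_order_parameter
#' @return Mean orientation in degrees, in `[0, 180)`.
#' @export
#' @examples
#' mean_direction(c(10, 170))  # 0, not 90
mean_direction <- function(angle_deg, w = NULL) {
  if (length(angle_deg) == 0L) return(NA_real_)
  th <- deg2rad(2 * angle_deg)
  if (is.null(w)) w <- rep(1, length(th))
  z <- sum(w * exp(1i * th))
  if (Mod(z) == 0) return(0)
  wrap_axial(rad2deg(Arg(z)) / 2)
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 falls
# back to the uniform circle. Returns radians on (-pi, pi].
rvonmises_rad <- function(n, mu, kappa) {
  if (kappa < 1e-8) {
    return(stats::runif(n, -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f) + mu
      i <- i + 1L
    }
  }
  (out + pi) %% (2 * pi) - pi
}

#' Sample axial orientations from a von Mises law on doubled angles
#'
#' Standard axial-data construction: draw `2 * theta` from a von Mises
#' distribution centered on `2 * mean_deg` with concentration `kappa`,
#' then halve. `kappa = 0` gives isotropic orientations.
#'
#' @param n Number of angles.
#' @param mean_deg Mean orientation in degrees.
#' @param kappa Concentration (on the doubled angles); non-negative.
#' @return Angles in degrees in `[0, 180)`.
#' @export
sample_axial_vonmises <- function(n, mean_deg, kappa) {
  stopifnot(kappa >= 0)
  th2 <- rvonmises_rad(n, deg2rad(2 * mean_deg), kappa)
  wrap_axial(rad2deg(th2) / 2)
}
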