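#' Per-pixel fiber orientation by the structure tensor
#'
#' Computes the local axial orientation (axis of least intensity variation,
#' i.e. the fiber axis for curvilinear structures) and a coherence measure
#' from the Gaussian-smoothed structure tensor of the image. Coherence is
#' `(l1 - l2) / (l1 + l2)` of the tensor eigenvalues: 1 for a perfectly
#' oriented neighborhood, 0 where the image is locally isotropic.
#'
#' @param image A [fiber_image()] (or plain matrix, pixel size 1 um).
#' @param sigma_um Integration scale of the tensor smoothing in um; must be
#'   at least one pixel.
#' @return An object of class `orientation_field`: list with matrices
#'   `angle_deg` (in `[0, 180)`, image convention), `coherence` (in
#'   `[0, 1]`), plus `sigma_um`, `pixel_size_um` and a `flat` flag set when
#'   the image has no local structure anywhere (angles then default to 0).
#' @export
#' @examples
#' ph <- generate_fiber_image(morphology_params("high_risk"), seed = 1)
#' of <- orientation_field(ph$image, sigma_um = 2)
#' mean(of$coherence)
orientation_field <- function(image, sigma_um) {
  if (!inherits(image, "fiber_image")) image <- fiber_image(as.matrix(image), 1)
  px <- image$pixel_size_um
  if (sigma_um < px) stop("sigma_um must be at least one pixel", call. = FALSE)
  m <- image$pixels
  # presmooth at one pixel to regularize the gradient
  ms <- gaussian_blur(m, 1)
  gx <- central_diff_cols(ms) / px
  gy <- central_diff_rows(ms) / px
  s <- sigma_um / px
  Jxx <- gaussian_blur(gx * gx, s)
  Jyy <- gaussian_blur(gy * gy, s)
  Jxy <- gaussian_blur(gx * gy, s)
  tr <- Jxx + Jyy
  disc <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2)
  eps <- 1e-12 * max(tr, 1e-300)
  coherence <- ifelse(tr > eps, disc / (tr + eps), 0)
  # gradient (max-variation) orientation, fiber axis is perpendicular
  theta_grad <- 0.5 * atan2(2 * Jxy, Jxx - Jyy)
  angle <- wrap_axial(rad2deg(theta_grad) + 90)
  flat <- max(tr) <= eps
  if (flat) angle[] <- 0
  structure(list(
    angle_deg = angle, coherence = pmin(pmax(coherence, 0), 1),
    sigma_um = sigma_um, pixel_size_um = px, flat = flat
  ), class = "orientation_field")
}

central_diff_cols <- function(m) {
  nc <- ncol(m)
  out <- matrix(0, nrow(m), nc)
  out[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  out
}

central_diff_rows <- function(m) {
  nr <- nrow(m)
  out <- matrix(0, nr, ncol(m))
  out[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  out
}

#' Binned axial orientation distribution
#'
#' Builds a normalized histogram of orientations over `[0, 180)`, either
#' from an [orientation_field()] (optionally masked, weighted by coherence,
#' image intensity, or uniformly) or from a plain vector of angles.
#'
#' @param x An `orientation_field`, or a numeric vector of angles in
#'   degrees.
#' @param n_bins Number of bins (>= 8); default 36 bins of 5 degrees.
#' @param mask Optional logical matrix restricting the field pixels used.
#' @param weight One of `"coherence"`, `"intensity"`, `"uniform"` (field
#'   input), or a numeric vector of weights (vector input).
#' @param image Required when `weight = "intensity"`: the [fiber_image()]
#'   the field was computed from.
#' @return An object of class `angular_distribution`: list with
#'   `bin_edges_deg` (length `n_bins + 1`, covering `[0, 180]`), `density`
#'   (sums to 1), `n_effective` (total weight).
#' @export
angular_distribution <- function(x, n_bins = 36L, mask = NULL,
                                 weight = c("coherence", "intensity", "uniform"),
                                 image = NULL) {
  if (n_bins < 8) stop("n_bins must be at least 8", call. = FALSE)
  if (inherits(x, "orientation_field")) {
    weight <- match.arg(weight)
    ang <- as.vector(x$angle_deg)
    w <- switch(weight,
      coherence = as.vector(x$coherence),
      intensity = {
        if (is.null(image)) stop("weight = 'intensity' needs `image`", call. = FALSE)
        as.vector(as_pixel_matrix(image))
      },
      uniform = rep(1, length(ang))
    )
    if (!is.null(mask)) {
      keep <- as.vector(mask)
      ang <- ang[keep]
      w <- w[keep]
    }
  } else {
    ang <- as.numeric(x)
    w <- if (is.numeric(weight)) weight else rep(1, length(ang))
    if (length(w) != length(ang)) stop("weights length mismatch", call. = FALSE)
  }
  ang <- wrap_axial(ang)
  edges <- seq(0, 180, length.out = n_bins + 1L)
  bin <- pmin(as.integer(floor(ang / 180 * n_bins)) + 1L, n_bins)
  dens <- vapply(seq_len(n_bins), function(k) sum(w[bin == k]), numeric(1))
  total <- sum(dens)
  if (total <= 0) stop("total weight is zero", call. = FALSE)
  structure(list(
    bin_edges_deg = edges,
    density = dens / total,
    n_effective = total
  ), class = "angular_distribution")
}

#' @export
print.angular_distribution <- function(x, ...) {
  cat(sprintf(
    "<angular_distribution> %d bins over [0,180), n_eff = %.4g, alignment index = %.3f\n",
    length(x$density), x$n_effective, alignment_index(x)
  ))
  invisible(x)
}

bin_centers <- function(dist) {
  e <- dist$bin_edges_deg
  (e[-1] + e[-length(e)]) / 2
}

#' Alignment index of an angular distribution
#'
#' Mean resultant length of the doubled bin-center angles under the binned
#' density: 0 for a uniform (isotropic) distribution, 1 for a single
#' occupied bin (perfect alignment).
#'
#' @param dist An [angular_distribution()].
#' @return Scalar in `[0, 1]`.
#' @export
alignment_index <- function(dist) {
  stopifnot(inherits(dist, "angular_distribution"))
  th <- deg2rad(2 * bin_centers(dist))
  Mod(sum(dist$density * exp(1i * th)))
}

#' Pearson correlation between two binned angular distributions
#'
#' Used to relate cellular stress-fiber orientation distributions to the
#' collagen fiber orientation distribution of the scaffold they sit on.
#' Requires identical binning; no silent rebinning is performed.
#'
#' @param dist_a,dist_b [angular_distribution()] objects on identical bins.
#' @return Pearson correlation of the density vectors, in `[-1, 1]`.
#' @export
pearson_between <- function(dist_a, dist_b) {
  stopifnot(inherits(dist_a, "angular_distribution"),
            inherits(dist_b, "angular_distribution"))
  if (length(dist_a$bin_edges_deg) != length(dist_b$bin_edges_deg) ||
      any(abs(dist_a$bin_edges_deg - dist_b$bin_edges_deg) > 1e-9)) {
    stop("distributions have different bin edges; rebin explicitly first",
         call. = FALSE)
  }
  stats::cor(dist_a$density, dist_b$density)
}

#' Two-sample Watson's U2 test for axial orientation data
#'
#' Tests whether two samples of orientations come from the same distribution
#' on the circle. Angles are doubled (axial to circular), the classical
#' two-sample Watson U2 statistic is computed from the combined ranked
#' sample, and the p-value is obtained by random permutation of group
#' labels, making the test exact under exchangeability at any sample size.
#'
#' @param angles_a,angles_b Samples of angles in degrees (axial, mod 180);
#'   at least 8 each.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @return An object of class `watson_u2`: list with `u2`, `p_value`,
#'   `n1`, `n2`, `n_permutations`.
#' @export
#' @examples
#' a <- sample_axial_vonmises(50, 0, 4)
#' b <- sample_axial_vonmises(50, 90, 4)
#' watson_u2(a, b, seed = 1)
watson_u2 <- function(angles_a, angles_b, n_permutations = 999L, seed = NULL) {
  n1 <- length(angles_a)
  n2 <- length(angles_b)
  if (n1 < 8 || n2 < 8) stop("need at least 8 angles per sample", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  # axial -> circular: double the angles
  z <- c(wrap_axial(angles_a) * 2, wrap_axial(angles_b) * 2)
  ord <- order(z)
  is_a <- c(rep(TRUE, n1), rep(FALSE, n2))[ord]
  u2 <- watson_u2_stat(is_a, n1, n2)
  perm <- replicate(n_permutations, watson_u2_stat(sample(is_a), n1, n2))
  p <- (1 + sum(perm >= u2)) / (n_permutations + 1)
  structure(list(u2 = u2, p_value = p, n1 = n1, n2 = n2,
                 n_permutations = as.integer(n_permutations)),
            class = "watson_u2")
}

# U2 from the group membership of the combined *sorted* sample; depends on
# the data only through the interleaving, so label permutation is exact.
watson_u2_stat <- function(is_a_sorted, n1, n2) {
  N <- n1 + n2
  d <- cumsum(is_a_sorted) / n1 - cumsum(!is_a_sorted) / n2
  (n1 * n2 / N^2) * (sum(d^2) - sum(d)^2 / N)
}

#' @export
print.watson_u2 <- function(x, ...) {
  cat(sprintf(
    "Two-sample Watson's U2 (axial data): U2 = %.4f, p = %.4g (n1 = %d, n2 = %d, %d permutations)\n",
    x$u2, x$p_value, x$n1, x$n2, x$n_permutations
  ))
  invisible(x)
}
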