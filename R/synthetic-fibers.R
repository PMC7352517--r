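#' Morphology presets for the four ovarian stromal classes
#'
#' Parameter sets describing fibrous-matrix phantoms that emulate the four
#' stromal morphologies seen in second-harmonic generation images of ovarian
#' tissue: normal stroma (mesh-like, randomly oriented straight fibers),
#' benign tumor (random but thicker, more fibrotic fibers), high-risk
#' (aligned straight fibers), and high-grade tumor (aligned fibers with a
#' periodic crimp). Alignment is controlled by the von Mises concentration
#' `orientation_kappa` on doubled angles (0 = isotropic); waviness by a
#' sinusoidal crimp of amplitude `crimp_amplitude_um` and wavelength
#' `crimp_wavelength_um`.
#'
#' Fields not quantified for these tissue classes (fiber width, length,
#' crimp wavelength) carry plausible defaults at the scale of the source
#' imagery; they are parameters, not calibrated measurements.
#'
#' @param class_label One of `"normal"`, `"benign"`, `"high_risk"`,
#'   `"high_grade"`.
#' @param ... Named overrides of any preset field (see Details).
#'
#' @details Fields: `image_size_px` (rows, cols), `pixel_size_um`,
#'   `n_fibers`, `fiber_width_um` (FWHM of the Gaussian cross-section),
#'   `fiber_length_um`, `orientation_mean_deg` in `[0, 180)`,
#'   `orientation_kappa` (>= 0), `crimp_amplitude_um` (>= 0),
#'   `crimp_wavelength_um` (> 0), `peak_intensity` (> 0, photon counts at the
#'   brightest pixel), `background_level` (>= 0), `noise_model` (`"poisson"`,
#'   `"gaussian"`, or `"none"`), `noise_sd` (for `"gaussian"`).
#'
#' @return A list of class `morphology_params`.
#' @export
#' @examples
#' p <- morphology_params("high_grade")
#' p$orientation_kappa
morphology_params <- function(class_label = c("normal", "benign", "high_risk",
                                              "high_grade"),
                              ...) {
  class_label <- match.arg(class_label)
  base <- list(
    class_label = class_label,
    image_size_px = c(400L, 400L),
    pixel_size_um = 0.5,
    n_fibers = 60L,
    fiber_width_um = 1.5,
    fiber_length_um = 80,
    orientation_mean_deg = 90,
    orientation_kappa = 0,
    crimp_amplitude_um = 0,
    crimp_wavelength_um = 25,
    peak_intensity = 400,
    background_level = 10,
    noise_model = "poisson",
    noise_sd = 5
  )
  preset <- switch(class_label,
    normal = list(fiber_length_um = 50),
    benign = list(fiber_width_um = 3, n_fibers = 40L, fiber_length_um = 50),
    high_risk = list(orientation_kappa = 8),
    high_grade = list(orientation_kappa = 8, crimp_amplitude_um = 3)
  )
  base[names(preset)] <- preset
  override <- list(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(base))
    if (length(bad)) stop("unknown morphology fields: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    base[names(override)] <- override
  }
  validate_morphology_params(base)
  structure(base, class = "morphology_params")
}

validate_morphology_params <- function(p) {
  if (length(p$image_size_px) != 2L || any(p$image_size_px <= 0)) {
    stop("image_size_px must be two positive integers", call. = FALSE)
  }
  if (p$pixel_size_um <= 0) stop("pixel_size_um must be > 0", call. = FALSE)
  if (p$n_fibers < 0) stop("n_fibers must be >= 0", call. = FALSE)
  if (p$fiber_width_um <= 0) stop("fiber_width_um must be > 0", call. = FALSE)
  if (p$fiber_length_um <= 0) stop("fiber_length_um must be > 0", call. = FALSE)
  if (p$orientation_kappa < 0) stop("orientation_kappa must be >= 0", call. = FALSE)
  if (p$crimp_amplitude_um < 0) stop("crimp_amplitude_um must be >= 0", call. = FALSE)
  if (p$crimp_wavelength_um <= 0) stop("crimp_wavelength_um must be > 0", call. = FALSE)
  if (p$peak_intensity <= 0) stop("peak_intensity must be > 0", call. = FALSE)
  if (p$background_level < 0) stop("background_level must be >= 0", call. = FALSE)
  invisible(p)
}

#' Generate a seeded fibrous-matrix phantom with ground truth
#'
#' Renders `n_fibers` fibers as curves with a Gaussian cross-section of the
#' requested width. Each fiber's orientation is drawn from a von Mises law on
#' doubled angles (axial data); a non-zero crimp amplitude adds a sinusoidal
#' lateral displacement `A * sin(2*pi*s / lambda)` along the fiber frame,
#' producing the wavy, periodic fibers characteristic of high-grade tumor
#' stroma. Background and photon (Poisson) or Gaussian noise are added last.
#'
#' @param params A [morphology_params()] object.
#' @param seed Integer seed; identical seeds give identical phantoms.
#' @return A list of class `fiber_phantom` with elements
#'   * `image`: a [fiber_image()],
#'   * `centerlines`: tibble (`fiber_id`, `point_index`, `x_um`, `y_um`,
#'     `local_angle_deg`) of ground-truth centerline samples,
#'   * `fibers`: tibble (`fiber_id`, `orientation_deg`) of per-fiber axis
#'     orientations,
#'   * `params`: the parameters used.
#' @export
#' @examples
#' ph <- generate_fiber_image(morphology_params("high_grade"), seed = 1)
#' ph$image
#' head(ph$centerlines)
generate_fiber_image <- function(params, seed) {
  stopifnot(inherits(params, "morphology_params"))
  validate_morphology_params(params)
  withr::local_seed(as.integer(seed))

  nr <- as.integer(params$image_size_px[1])
  nc <- as.integer(params$image_size_px[2])
  px <- params$pixel_size_um
  height_um <- nr * px
  width_um <- nc * px

  canvas <- matrix(0, nr, nc)
  n <- params$n_fibers
  centerlines <- list()
  orientations <- numeric(0)

  if (n > 0) {
    orientations <- sample_axial_vonmises(n, params$orientation_mean_deg,
                                          params$orientation_kappa)
    # centerline sampled finely relative to the pixel grid
    step_um <- px / 4
    L <- params$fiber_length_um
    s <- seq(-L / 2, L / 2, by = step_um)
    A <- params$crimp_amplitude_um
    lam <- params$crimp_wavelength_um
    for (i in seq_len(n)) {
      th <- deg2rad(orientations[i])
      ct <- cos(th); st <- sin(th)
      cx <- stats::runif(1, 0, width_um)
      cy <- stats::runif(1, 0, height_um)
      phase <- stats::runif(1, 0, 2 * pi)
      off <- if (A > 0) A * sin(2 * pi * s / lam + phase) else numeric(length(s)) * 0
      doff <- if (A > 0) A * (2 * pi / lam) * cos(2 * pi * s / lam + phase) else numeric(length(s)) * 0
      # fiber frame: along-axis s, lateral offset along the normal (-st, ct)
      x <- cx + s * ct - off * st
      y <- cy + s * st + off * ct
      local_angle <- wrap_axial(orientations[i] + rad2deg(atan(doff)))
      keep <- x >= 0 & x < width_um & y >= 0 & y < height_um
      if (any(keep)) {
        rows <- pmin(nr, pmax(1L, as.integer(floor(y[keep] / px)) + 1L))
        cols <- pmin(nc, pmax(1L, as.integer(floor(x[keep] / px)) + 1L))
        # accumulate step mass (handles duplicate pixels along the curve)
        lin <- (cols - 1L) * nr + rows
        canvas <- canvas + tabulate(lin, nbins = nr * nc)
      }
      centerlines[[i]] <- tibble::tibble(
        fiber_id = i,
        point_index = seq_along(s)[keep],
        x_um = x[keep],
        y_um = y[keep],
        local_angle_deg = local_angle[keep]
      )
    }
    sigma_px <- params$fiber_width_um / (2 * sqrt(2 * log(2))) / px
    canvas <- gaussian_blur(canvas, sigma_px)
    canvas[canvas < 0] <- 0
    if (max(canvas) > 0) canvas <- canvas / max(canvas)
  }

  noiseless <- canvas * params$peak_intensity + params$background_level
  pixels <- apply_noise(noiseless, params$noise_model, params$noise_sd)

  structure(list(
    image = fiber_image(pixels, px),
    centerlines = if (length(centerlines)) dplyr::bind_rows(centerlines)
                  else tibble::tibble(fiber_id = integer(), point_index = integer(),
                                      x_um = numeric(), y_um = numeric(),
                                      local_angle_deg = numeric()),
    fibers = tibble::tibble(fiber_id = seq_len(n), orientation_deg = orientations),
    params = params
  ), class = "fiber_phantom")
}

apply_noise <- function(noiseless, noise_model, noise_sd) {
  out <- switch(noise_model,
    poisson = matrix(stats::rpois(length(noiseless), lambda = noiseless),
                     nrow = nrow(noiseless)),
    gaussian = noiseless + matrix(stats::rnorm(length(noiseless), sd = noise_sd),
                                  nrow = nrow(noiseless)),
    none = noiseless,
    stop("unknown noise_model: ", noise_model, call. = FALSE)
  )
  out[out < 0] <- 0
  out
}
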