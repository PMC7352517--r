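#' Generate an elliptical cell mask
#'
#' Rasterizes an ellipse of given spread area, aspect ratio, and major-axis
#' orientation, used as a synthetic cell outline for shape and fluorescence
#' quantification. The center is jittered by up to half a pixel so that
#' different seeds sample different digitizations of the same ellipse.
#'
#' @param aspect_ratio Major/minor axis ratio (>= 1).
#' @param area_um2 Spread area in um^2 (> 0); must yield at least 100
#'   foreground pixels at the given pixel size.
#' @param angle_deg Major-axis orientation in degrees (axial, image
#'   convention: measured from +x, y pointing down).
#' @param pixel_size_um Pixel size in um (> 0).
#' @param seed Integer seed (sub-pixel center jitter only).
#' @param image_size_px Optional (rows, cols); defaults to a snug frame with
#'   a margin. If supplied and the ellipse does not fit, an error is raised.
#' @return A logical matrix (the mask) with attributes `pixel_size_um` and
#'   `center_px`.
#' @export
#' @examples
#' m <- generate_cell_mask(aspect_ratio = 2, area_um2 = 500, angle_deg = 30,
#'                         pixel_size_um = 0.5, seed = 1)
#' sum(m) * 0.25  # area in um^2, close to 500
generate_cell_mask <- function(aspect_ratio, area_um2, angle_deg,
                               pixel_size_um, seed, image_size_px = NULL) {
  stopifnot(aspect_ratio >= 1, area_um2 > 0, pixel_size_um > 0)
  if (area_um2 / pixel_size_um^2 < 100) {
    stop("area_um2 yields fewer than 100 foreground pixels at this pixel size",
         call. = FALSE)
  }
  withr::local_seed(as.integer(seed))
  a <- sqrt(area_um2 * aspect_ratio / pi)  # semi-major, um
  b <- sqrt(area_um2 / (pi * aspect_ratio))
  a_px <- a / pixel_size_um
  b_px <- b / pixel_size_um
  if (is.null(image_size_px)) {
    half <- ceiling(a_px) + 3L
    image_size_px <- c(2L * half + 1L, 2L * half + 1L)
  }
  nr <- image_size_px[1]; nc <- image_size_px[2]
  cy <- (nr + 1) / 2 + stats::runif(1, -0.5, 0.5)
  cx <- (nc + 1) / 2 + stats::runif(1, -0.5, 0.5)
  if (cx - a_px < 0 || cx + a_px > nc || cy - a_px < 0 || cy + a_px > nr) {
    stop("ellipse does not fit inside image_size_px", call. = FALSE)
  }
  th <- deg2rad(angle_deg)
  col <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  row <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  dx <- col - cx
  dy <- row - cy
  u <- dx * cos(th) + dy * sin(th)    # along major axis
  v <- -dx * sin(th) + dy * cos(th)   # along minor axis
  mask <- (u / a_px)^2 + (v / b_px)^2 <= 1
  attr(mask, "pixel_size_um") <- pixel_size_um
  attr(mask, "center_px") <- c(row = cy, col = cx)
  mask
}

#' Parameters for the punctate spot-field generator
#'
#' Describes a synthetic immunofluorescence image of punctate focal
#' adhesions: isotropic Gaussian spots scattered uniformly inside a cell
#' mask, over a diffuse cell background, with additive Gaussian noise.
#'
#' @param n_spots Number of spots (>= 0).
#' @param spot_sigma_um Gaussian sigma of each spot in um (> 0).
#' @param spot_amplitude Peak amplitude of each spot (> 0).
#' @param cell_background Diffuse intensity added inside the mask (>= 0).
#' @param noise_sd Additive Gaussian noise sd (>= 0).
#' @param cell_mask Logical matrix with a `pixel_size_um` attribute (e.g.
#'   from [generate_cell_mask()]).
#' @return A list of class `spot_field_params`.
#' @export
spot_field_params <- function(n_spots, spot_sigma_um, spot_amplitude,
                              cell_background, noise_sd, cell_mask) {
  stopifnot(n_spots >= 0, spot_sigma_um > 0, spot_amplitude > 0,
            cell_background >= 0, noise_sd >= 0, is.matrix(cell_mask))
  px <- attr(cell_mask, "pixel_size_um")
  if (is.null(px)) stop("cell_mask needs a pixel_size_um attribute", call. = FALSE)
  if (spot_sigma_um < px) {
    stop("spot_sigma_um must be at least one pixel", call. = FALSE)
  }
  structure(list(
    n_spots = as.integer(n_spots), spot_sigma_um = spot_sigma_um,
    spot_amplitude = spot_amplitude, cell_background = cell_background,
    noise_sd = noise_sd, cell_mask = cell_mask, pixel_size_um = px
  ), class = "spot_field_params")
}

#' Generate a punctate spot image with ground-truth centers
#'
#' Places `n_spots` Gaussian spots at positions sampled uniformly among
#' in-mask pixels (with sub-pixel jitter), adds the diffuse cell background
#' inside the mask and Gaussian read noise everywhere.
#'
#' @param params A [spot_field_params()] object.
#' @param seed Integer seed.
#' @return A list of class `spot_phantom`: `image` (a [fiber_image()]),
#'   `spots` (tibble `spot_id`, `x_um`, `y_um`), `params`.
#' @export
generate_spot_image <- function(params, seed) {
  stopifnot(inherits(params, "spot_field_params"))
  withr::local_seed(as.integer(seed))
  mask <- params$cell_mask
  px <- params$pixel_size_um
  nr <- nrow(mask); nc <- ncol(mask)
  img <- matrix(0, nr, nc)
  img[mask] <- params$cell_background

  n <- params$n_spots
  if (n > 0) {
    inside <- which(mask)
    pick <- sample(inside, n, replace = FALSE)
    rows <- ((pick - 1L) %% nr) + 1L
    cols <- ((pick - 1L) %/% nr) + 1L
    x_um <- (cols - 1L + stats::runif(n)) * px
    y_um <- (rows - 1L + stats::runif(n)) * px
    sig_px <- params$spot_sigma_um / px
    half <- ceiling(4 * sig_px)
    for (i in seq_len(n)) {
      r0 <- y_um[i] / px + 0.5  # pixel-center coordinates
      c0 <- x_um[i] / px + 0.5
      rr <- max(1L, floor(r0 - half)):min(nr, ceiling(r0 + half))
      cc <- max(1L, floor(c0 - half)):min(nc, ceiling(c0 + half))
      g <- params$spot_amplitude *
        exp(-(outer((rr - r0)^2, (cc - c0)^2, "+")) / (2 * sig_px^2))
      img[rr, cc] <- img[rr, cc] + g
    }
    spots <- tibble::tibble(spot_id = seq_len(n), x_um = x_um, y_um = y_um)
  } else {
    spots <- tibble::tibble(spot_id = integer(), x_um = numeric(),
                            y_um = numeric())
  }

  if (params$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(nr * nc, sd = params$noise_sd), nr, nc)
  }
  img[img < 0] <- 0
  structure(list(image = fiber_image(img, px), spots = spots, params = params),
            class = "spot_phantom")
}
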