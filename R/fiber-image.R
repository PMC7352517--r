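#' Calibrated grayscale image of a fibrous matrix
#'
#' A `fiber_image` is a plain numeric matrix of non-negative intensities
#' (rows are y, columns are x, origin at the top-left, y pointing down —
#' the usual image convention) plus the physical pixel size in micrometers.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param pixel_size_um Pixel size in micrometers per pixel (> 0).
#' @return An object of class `fiber_image`.
#' @export
#' @examples
#' img <- fiber_image(matrix(runif(100), 10, 10), pixel_size_um = 0.5)
#' dim(img$pixels)
fiber_image <- function(pixels, pixel_size_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels))) {
    stop("`pixels` contains non-finite values", call. = FALSE)
  }
  if (any(pixels < 0)) {
    stop("`pixels` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um)),
    class = "fiber_image"
  )
}

#' @export
print.fiber_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<fiber_image> %d x %d px (%.1f x %.1f um at %.3g um/px), intensity [%.3g, %.3g]\n",
    d[1], d[2], d[1] * x$pixel_size_um, d[2] * x$pixel_size_um,
    x$pixel_size_um, min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.fiber_image <- function(x) dim(x$pixels)

as_pixel_matrix <- function(x) {
  if (inherits(x, "fiber_image")) x$pixels else as.matrix(x)
}

# Gaussian blur that keeps plain-matrix semantics. EBImage::gblur uses a
# circular boundary; fine here because phantoms keep fibers away from edges
# and the blur scales used are a few pixels at most.
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  out <- EBImage::gblur(EBImage::Image(m), sigma = sigma_px)
  matrix(EBImage::imageData(out), nrow = nrow(m))
}

# Otsu threshold for an arbitrary-range matrix: rescale to [0,1], threshold,
# map back. Returns the threshold on the original intensity scale.
otsu_threshold <- function(m) {
  lo <- min(m)
  hi <- max(m)
  if (hi <= lo) return(hi)
  scaled <- (m - lo) / (hi - lo)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256L)
  lo + thr * (hi - lo)
}

# Connected-component labelling (8-connectivity) on a logical matrix.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  matrix(EBImage::imageData(lab), nrow = nrow(mask))
}

# Drop connected components smaller than min_px pixels.
remove_small_objects <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow = nrow(mask))
}
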