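#' Read and write calibrated images, blueprints, and tables
#'
#' Images travel as single-channel TIFF with the pixel size recorded in a
#' JSON sidecar (`<file>.json`, field `pixel_size_um`); trajectory tables,
#' orientation distributions and scan plans as plain CSV. Scan-plan open
#' fractions round-trip bit-exactly through full-precision text.
#'
#' @name matricell-io
NULL

sidecar_path <- function(path) paste0(path, ".json")

#' @describeIn matricell-io Write a [fiber_image()] as TIFF (32-bit float)
#'   plus a JSON sidecar with the pixel size.
#' @param image A [fiber_image()].
#' @param path Target file path (TIFF).
#' @export
write_fiber_image <- function(image, path) {
  stopifnot(inherits(image, "fiber_image"))
  m <- image$pixels
  tiff::writeTIFF(m / max(max(m), 1e-300), path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_size_um = image$pixel_size_um, intensity_scale = max(max(m), 1e-300)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @describeIn matricell-io Read a TIFF + sidecar back into a
#'   [fiber_image()].
#' @export
read_fiber_image <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path))
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  fiber_image(m * meta$intensity_scale, meta$pixel_size_um)
}

#' @describeIn matricell-io Write a blueprint: 16-bit TIFF of the graded
#'   map plus a JSON sidecar (pixel size, tile extent, height).
#' @param blueprint A [discretize_fibers()] result.
#' @export
write_blueprint <- function(blueprint, path) {
  stopifnot(inherits(blueprint, "blueprint"))
  tiff::writeTIFF(blueprint$graded, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size_um = blueprint$pixel_size_um,
         tile_um = blueprint$tile_um, height_um = blueprint$height_um),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @describeIn matricell-io Read a blueprint written by [write_blueprint()]
#'   (graded values quantized to 16 bits; mask = graded > 0).
#' @export
read_blueprint <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path))
  g <- tiff::readTIFF(path)
  if (length(dim(g)) == 3L) g <- g[, , 1]
  if (any(g > 0)) g <- g / max(g)
  new_blueprint(g > 0, g, meta$pixel_size_um,
                unlist(meta$tile_um), meta$height_um)
}

#' @describeIn matricell-io Write a trajectory table as CSV with header
#'   `track_id, frame, t_min, x_um, y_um` (frame 0-based, coordinates in
#'   um, image convention).
#' @param tracks Trajectory tibble.
#' @export
write_trajectories <- function(tracks, path) {
  check_trajectories(tracks)
  if (!"frame" %in% names(tracks)) {
    tracks <- tracks |>
      dplyr::group_by(.data$track_id) |>
      dplyr::mutate(frame = dplyr::row_number() - 1L) |>
      dplyr::ungroup()
  }
  utils::write.csv(tracks[c("track_id", "frame", "t_min", "x_um", "y_um")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @describeIn matricell-io Read a trajectory CSV.
#' @export
read_trajectories <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  check_trajectories(out)
  out
}

#' @describeIn matricell-io Write an [angular_distribution()] as CSV
#'   (`bin_start_deg, bin_end_deg, density`).
#' @param dist An [angular_distribution()].
#' @export
write_angular_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "angular_distribution"))
  e <- dist$bin_edges_deg
  utils::write.csv(
    data.frame(bin_start_deg = e[-length(e)], bin_end_deg = e[-1],
               density = dist$density),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @describeIn matricell-io Write a scan plan: CSV of
#'   `row, col, open_fraction` at full precision (bit-exact round trip)
#'   plus a JSON header with dwell, tiles and extent.
#' @param plan A [build_scan_plan()] result.
#' @export
write_scan_plan <- function(plan, path) {
  stopifnot(inherits(plan, "scan_plan"))
  of <- plan$open_fraction
  df <- data.frame(
    row = rep(seq_len(nrow(of)), times = ncol(of)),
    col = rep(seq_len(ncol(of)), each = nrow(of)),
    open_fraction = sprintf("%.17g", as.vector(of))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(dwell_us = plan$dwell_us, tiles = plan$tiles,
         overall_extent_um = plan$overall_extent_um,
         n_rows = nrow(of), n_cols = ncol(of)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @describeIn matricell-io Read a scan plan written by
#'   [write_scan_plan()].
#' @export
read_scan_plan <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path))
  df <- utils::read.csv(path)
  of <- matrix(NA_real_, meta$n_rows, meta$n_cols)
  of[cbind(df$row, df$col)] <- as.numeric(df$open_fraction)
  structure(list(
    open_fraction = of, dwell_us = meta$dwell_us,
    tiles = as.integer(unlist(meta$tiles)),
    overall_extent_um = as.numeric(unlist(meta$overall_extent_um))
  ), class = "scan_plan")
}

#' @describeIn matricell-io Write a [watson_u2()] result as JSON.
#' @param x A `watson_u2` object.
#' @export
write_watson_u2 <- function(x, path) {
  stopifnot(inherits(x, "watson_u2"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
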