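#' Scan protocol metadata
#'
#' Describes an OCT raster scan: lateral field of view, A-lines per B-frame,
#' number of slow-axis (y) locations, repeated B-frames per location, frame
#' rate, axial range and axial pixel pitch. A typical wide-field skin protocol
#' covers 5 mm x 5 mm with 256 A-lines per frame, 256 y locations and 8
#' repeats at 100 frames/s.
#'
#' @param fov_x_mm,fov_y_mm lateral field of view (mm), fast and slow axis.
#' @param n_alines A-lines per B-frame (fast-axis pixel count).
#' @param n_y number of slow-axis spatial locations.
#' @param n_repeats repeated B-frames per y location.
#' @param frame_rate_hz B-frame rate (frames/s).
#' @param axial_pitch_um axial pixel pitch (um per voxel).
#' @param axial_range_mm imaging range in depth (mm), optional metadata.
#' @return An object of class \code{scan_protocol}.
#' @export
scan_protocol <- function(fov_x_mm, fov_y_mm = fov_x_mm, n_alines, n_y,
                          n_repeats = 1L, frame_rate_hz = 100,
                          axial_pitch_um = 8, axial_range_mm = NA_real_) {
  stopifnot(fov_x_mm > 0, fov_y_mm > 0, frame_rate_hz > 0, axial_pitch_um > 0)
  n_alines <- as.integer(n_alines); n_y <- as.integer(n_y)
  n_repeats <- as.integer(n_repeats)
  if (n_alines < 1L || n_y < 1L || n_repeats < 1L)
    stop("all scan counts must be >= 1")
  structure(list(
    fov_x_mm = fov_x_mm, fov_y_mm = fov_y_mm,
    n_alines = n_alines, n_y = n_y, n_repeats = n_repeats,
    frame_rate_hz = frame_rate_hz,
    axial_pitch_um = axial_pitch_um, axial_range_mm = axial_range_mm
  ), class = "scan_protocol")
}

#' Lateral pixel spacing of a scan protocol
#'
#' Field of view divided by pixel count per lateral axis, in micrometres.
#' A 5 mm field sampled with 256 A-lines gives 19.53 um, commonly quoted
#' as ~20 um spacing.
#'
#' @param protocol a \code{scan_protocol}.
#' @return Named numeric vector \code{c(x = , y = )}, um per pixel.
#' @export
lateral_pixel_spacing <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  if (protocol$n_alines < 1L || protocol$n_y < 1L) stop("zero pixel count")
  c(x = 1000 * protocol$fov_x_mm / protocol$n_alines,
    y = 1000 * protocol$fov_y_mm / protocol$n_y)
}

#' Total B-frames captured by a protocol
#'
#' @param protocol a \code{scan_protocol}.
#' @return Integer: y locations times repeats.
#' @export
total_bframes <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  protocol$n_y * protocol$n_repeats
}

#' Scan duration of a protocol
#'
#' @param protocol a \code{scan_protocol}.
#' @return Seconds: total B-frames divided by frame rate.
#' @export
scan_duration <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  total_bframes(protocol) / protocol$frame_rate_hz
}

#' @export
print.scan_protocol <- function(x, ...) {
  sp <- lateral_pixel_spacing(x)
  cat(sprintf(
    "scan_protocol: %.3g x %.3g mm, %d A-lines x %d y-locations x %d repeats\n",
    x$fov_x_mm, x$fov_y_mm, x$n_alines, x$n_y, x$n_repeats))
  cat(sprintf("  %.2f/%.2f um lateral spacing (x/y), %d B-frames, %.2f s at %g fps\n",
              sp["x"], sp["y"], total_bframes(x), scan_duration(x), x$frame_rate_hz))
  invisible(x)
}
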