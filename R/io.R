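# Volume I/O: multi-page 32-bit TIFF or raw binary, plus a JSON sidecar.
#
# Page order is (y outer, repeat inner); a complex volume stores two pages
# per B-frame (real then imaginary), declared by `dtype` in the sidecar.
# TIFF pages hold values affinely rescaled to [0, 1] (the scale is recorded in
# the sidecar and undone on read); raw binary stores IEEE float32 verbatim, so
# it round-trips bit-exactly at single precision. The pixel file carries data
# only; every protocol field lives in the sidecar (<path>.json), and a stack
# without its sidecar is rejected.

sidecar_path <- function(path) paste0(path, ".json")

volume_format <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
  else if (grepl("\\.(bin|raw)$", path, ignore.case = TRUE)) "raw"
  else stop("unrecognized volume extension (want .tif/.tiff or .bin/.raw): ", path)
}

# Planes of a volume in storage order: (y outer, repeat inner), complex split
# into (real, imag) pairs.
volume_planes <- function(volume) {
  d <- dim(volume$data)
  cx <- volume$mode == "complex"
  pages <- vector("list", d[3] * d[4] * (1L + cx))
  k <- 1L
  for (iy in seq_len(d[4])) for (ir in seq_len(d[3])) {
    frame <- volume$data[, , ir, iy]
    if (cx) {
      pages[[k]] <- Re(frame); pages[[k + 1L]] <- Im(frame); k <- k + 2L
    } else {
      pages[[k]] <- frame; k <- k + 1L
    }
  }
  pages
}

#' Write a repeated-B-scan volume with a JSON sidecar
#'
#' Two storage formats, selected by the file extension: multi-page TIFF
#' (\code{.tif}/\code{.tiff}; 32-bit pages rescaled to [0, 1] with the scale
#' recorded in the sidecar) or raw binary (\code{.bin}/\code{.raw}; IEEE
#' float32, column-major, exact at single precision). Pages/planes are ordered
#' y-outer, repeat-inner; complex volumes store (real, imaginary) plane pairs.
#' The scan protocol and layout go to \code{<path>.json}.
#'
#' @param volume a \code{\link{bscan_volume}}.
#' @param path output filename; the sidecar is written next to it.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "bscan_volume"))
  d <- dim(volume$data)
  if (any(d == 0L) || length(volume$data) == 0L)
    stop("cannot write an empty volume")
  fmt <- volume_format(path)
  pages <- volume_planes(volume)
  value_range <- NULL
  if (fmt == "tiff") {
    lo <- min(vapply(pages, min, 0)); hi <- max(vapply(pages, max, 0))
    if (hi <= lo) hi <- lo + 1
    tiff::writeTIFF(lapply(pages, function(p) (p - lo) / (hi - lo)),
                    path, bits.per.sample = 32L)
    value_range <- c(lo, hi)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    for (p in pages) writeBin(as.numeric(p), con, size = 4L, endian = "little")
  }
  meta <- list(
    format = "olagr-volume", version = 1L, storage = fmt,
    dtype = if (volume$mode == "complex") "complex64" else "float32",
    mode = volume$mode, source = volume$source,
    dims = list(nz = d[1], nx = d[2], n_repeats = d[3], n_y = d[4]),
    page_order = "y-outer, repeat-inner; complex as (real, imag) plane pairs",
    value_range = value_range,
    protocol = unclass(volume$protocol)
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a repeated-B-scan volume written by \code{write_volume}
#'
#' @param path TIFF or raw filename with a \code{<path>.json} sidecar.
#' @return A \code{\link{bscan_volume}} with \code{source = "file"}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing JSON sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!identical(meta$format, "olagr-volume"))
    stop("sidecar is not an olagr volume descriptor: ", sc)
  dm <- meta$dims
  cx <- meta$mode == "complex"
  n_planes <- dm$n_y * dm$n_repeats * (1L + cx)
  plane_len <- dm$nz * dm$nx
  if (meta$storage == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != n_planes)
      stop(sprintf("page count mismatch: sidecar implies %d pages, TIFF has %d",
                   n_planes, length(pages)))
    vr <- meta$value_range
    pages <- lapply(pages, function(p) p * (vr[2] - vr[1]) + vr[1])
  } else {
    sz <- file.info(path)$size
    if (sz != 4 * n_planes * plane_len)
      stop(sprintf("raw size mismatch: sidecar implies %d planes of %d values, file has %.0f bytes",
                   n_planes, plane_len, sz))
    con <- file(path, "rb")
    on.exit(close(con))
    pages <- replicate(n_planes, matrix(
      readBin(con, "numeric", plane_len, size = 4L, endian = "little"),
      dm$nz, dm$nx), simplify = FALSE)
  }
  pf <- as.list(meta$protocol)
  fields <- c("fov_x_mm", "fov_y_mm", "n_alines", "n_y", "n_repeats",
              "frame_rate_hz", "axial_pitch_um", "axial_range_mm")
  args <- lapply(fields, function(f) {
    v <- pf[[f]]
    if (is.null(v)) NA_real_ else v   # nullable metadata (e.g. axial range)
  })
  names(args) <- fields
  proto <- do.call(scan_protocol, args)
  data <- array(if (cx) complex(real = 0) else 0,
                c(dm$nz, dm$nx, dm$n_repeats, dm$n_y))
  k <- 1L
  for (iy in seq_len(dm$n_y)) for (ir in seq_len(dm$n_repeats)) {
    if (cx) {
      data[, , ir, iy] <- complex(real = pages[[k]], imaginary = pages[[k + 1L]])
      k <- k + 2L
    } else {
      data[, , ir, iy] <- pages[[k]]
      k <- k + 1L
    }
  }
  bscan_volume(data, proto, mode = meta$mode, source = "file")
}

#' Write an en-face image as a 16-bit grayscale TIFF
#'
#' Values are min-max scaled to [0, 1] unless a fixed \code{range} is given.
#'
#' @param img numeric matrix (x by y).
#' @param path output filename.
#' @param range optional c(lo, hi) used for scaling; defaults to the data range.
#' @return \code{path}, invisibly.
#' @export
write_enface <- function(img, path, range = NULL) {
  r <- range %||% base::range(img, finite = TRUE)
  if (r[2] <= r[1]) r[2] <- r[1] + 1
  scaled <- pmin(pmax((img - r[1]) / (r[2] - r[1]), 0), 1)
  scaled[!is.finite(scaled)] <- 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a boolean mask stack as a 1-bit-per-pixel style TIFF (0/1 values)
#'
#' @param mask logical array (x by y) or (z by x by y).
#' @param path output filename.
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1L))
  pages <- lapply(seq_len(dim(mask)[3]), function(i) (mask[, , i]) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
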