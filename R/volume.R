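#' Repeated-B-scan OCT volume
#'
#' Container for a volumetric OCT acquisition with repeated B-frames: a 4D
#' array indexed \code{[z, x, repeat, y]} (z index 1 = shallowest), either
#' complex-valued (full OCT signal) or real amplitude, plus its
#' \code{\link{scan_protocol}}.
#'
#' @param data 4D numeric or complex array \code{[z, x, repeat, y]}.
#' @param protocol a \code{scan_protocol}; repeat and lateral counts must match.
#' @param mode \code{"complex"} or \code{"amplitude"}; inferred from the array
#'   type when missing.
#' @param source provenance tag, e.g. \code{"phantom"} or \code{"file"}.
#' @return An object of class \code{bscan_volume} with elements \code{data},
#'   \code{protocol}, \code{mode}, \code{source}.
#' @export
bscan_volume <- function(data, protocol, mode = NULL, source = "unknown") {
  stopifnot(inherits(protocol, "scan_protocol"))
  if (length(dim(data)) != 4L)
    stop("data must be a 4D array [z, x, repeat, y]")
  d <- dim(data)
  if (d[2] != protocol$n_alines || d[3] != protocol$n_repeats || d[4] != protocol$n_y)
    stop(sprintf(
      "array dims [z=%d, x=%d, repeat=%d, y=%d] do not match protocol (x=%d, repeat=%d, y=%d)",
      d[1], d[2], d[3], d[4], protocol$n_alines, protocol$n_repeats, protocol$n_y))
  if (is.null(mode)) mode <- if (is.complex(data)) "complex" else "amplitude"
  mode <- match.arg(mode, c("complex", "amplitude"))
  if (mode == "amplitude" && is.complex(data))
    stop("amplitude mode requires a real array")
  if (!all(is.finite(Mod(data))))
    stop("volume contains non-finite values")
  structure(list(data = data, protocol = protocol, mode = mode, source = source),
            class = "bscan_volume")
}

#' Structural amplitude of a volume
#'
#' Modulus of the complex signal (or the amplitude itself), optionally averaged
#' over repeats to a 3D \code{[z, x, y]} array.
#'
#' @param volume a \code{bscan_volume}.
#' @param average_repeats collapse the repeat dimension by the mean amplitude.
#' @return 4D amplitude array, or 3D when \code{average_repeats}.
#' @export
structural_amplitude <- function(volume, average_repeats = TRUE) {
  stopifnot(inherits(volume, "bscan_volume"))
  a <- Mod(volume$data)
  if (!average_repeats) return(a)
  d <- dim(a)
  if (d[3] == 1L) {
    array(a, d[c(1, 2, 4)])
  } else {
    out <- array(0, d[c(1, 2, 4)])
    for (r in seq_len(d[3]))
      out <- out + array(a[, , r, , drop = FALSE], d[c(1, 2, 4)])
    out / d[3]
  }
}

#' @export
print.bscan_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bscan_volume (%s, %s): [z=%d, x=%d, repeat=%d, y=%d]\n",
              x$mode, x$source, d[1], d[2], d[3], d[4]))
  invisible(x)
}
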