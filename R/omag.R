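# Optical microangiography: blood-flow contrast from repeated B-frames.
#
# Moving scatterers (red blood cells) decorrelate the complex OCT signal
# between B-frames repeated at the same location, while static tissue and
# lymph lumens give a (nearly) constant signal. Flow is therefore contrasted
# by the mean absolute difference between adjacent repeats, after integer
# axial registration that removes bulk tissue motion.

#' Register repeated B-frames by global axial cross-correlation
#'
#' Each frame is shifted axially by the integer number of voxels that
#' maximizes the normalized cross-correlation of its amplitude against the
#' first frame (exhaustive search over \code{-max_shift:max_shift}). Vacated
#' rows are zero-filled; the returned \code{valid_rows} margin excludes rows
#' any frame vacated, so downstream statistics can ignore them.
#'
#' @param frames list of complex (or real) matrices \code{[z, x]}, equal dims.
#' @param max_shift search half-window in voxels; default \code{nz / 4}.
#' @return List: \code{frames} (aligned), \code{shifts} (integer per frame;
#'   the shift applied, so \code{-s} undoes an injected shift \code{+s}),
#'   \code{valid_rows} (logical over z).
#' @export
register_repeats <- function(frames, max_shift = NULL) {
  stopifnot(is.list(frames), length(frames) >= 2)
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), TRUE)))
    stop("all frames must have identical dimensions")
  nz <- d[1]
  max_shift <- as.integer(max_shift %||% max(1L, nz %/% 4L))
  ref <- Mod(frames[[1]])
  ref_c <- ref - mean(ref)
  shifts <- integer(length(frames))
  out <- frames
  for (i in seq_along(frames)[-1]) {
    a <- Mod(frames[[i]])
    if (all(a == 0) || all(ref == 0)) {
      warning("all-zero frame during registration; shift set to 0")
      shifts[i] <- 0L
      next
    }
    best <- -Inf; best_s <- 0L
    for (s in -max_shift:max_shift) {
      # rows where frame i shifted by s overlaps the reference
      if (s >= 0) { r1 <- 1:(nz - s); r2 <- (1 + s):nz } else { r1 <- (1 - s):nz; r2 <- 1:(nz + s) }
      u <- ref[r2, , drop = FALSE]; v <- a[r1, , drop = FALSE]
      u <- u - mean(u); v <- v - mean(v)
      den <- sqrt(sum(u^2) * sum(v^2))
      cc <- if (den > 0) sum(u * v) / den else -Inf
      if (cc > best) { best <- cc; best_s <- s }
    }
    shifts[i] <- best_s
    if (best_s != 0L) out[[i]] <- shift_axial(frames[[i]], best_s)
  }
  valid <- rep(TRUE, nz)
  for (s in shifts) {
    if (s > 0) valid[1:s] <- FALSE
    if (s < 0) valid[(nz + s + 1):nz] <- FALSE
  }
  list(frames = out, shifts = shifts, valid_rows = valid)
}

#' Compute a flow B-frame from aligned repeats
#'
#' Mean absolute adjacent-difference of the (complex) signal over repeats:
#' \deqn{flow(z,x) = \frac{1}{R-1}\sum_{i=1}^{R-1} |C_{i+1}(z,x) - C_i(z,x)|.}
#' With amplitude-only data the modulus is differenced instead. The result is
#' invariant to a global phase rotation of all repeats.
#'
#' @param frames list of R >= 2 aligned matrices \code{[z, x]}, complex or real.
#' @return Nonnegative flow matrix \code{[z, x]}.
#' @export
compute_flow <- function(frames) {
  stopifnot(is.list(frames))
  if (length(frames) < 2) stop("need at least 2 repeats to compute flow")
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), TRUE)))
    stop("all frames must have identical dimensions")
  acc <- matrix(0, d[1], d[2])
  for (i in seq_len(length(frames) - 1)) {
    acc <- acc + Mod(frames[[i + 1]] - frames[[i]])
  }
  acc / (length(frames) - 1)
}

#' Angiogram volume from a repeated-B-scan volume
#'
#' Runs \code{\link{register_repeats}} (optional) and \code{\link{compute_flow}}
#' per y location and stacks the flow frames into a \code{[z, x, y]} volume.
#' Rows invalidated by registration at a location are set to 0.
#'
#' @param volume a \code{\link{bscan_volume}} with >= 2 repeats.
#' @param register run bulk-motion registration first (default TRUE).
#' @param max_shift registration search half-window (voxels).
#' @return An object of class \code{angiogram}: \code{flow} \code{[z, x, y]},
#'   \code{shifts} (n_repeats x ny), \code{protocol}, \code{kernel} (none yet).
#' @export
omag_angiogram <- function(volume, register = TRUE, max_shift = NULL) {
  stopifnot(inherits(volume, "bscan_volume"))
  d <- dim(volume$data)
  if (d[3] < 2) stop("OMAG needs at least 2 repeats per location")
  flow <- array(0, d[c(1, 2, 4)])
  shifts <- matrix(0L, d[3], d[4])
  for (iy in seq_len(d[4])) {
    frames <- lapply(seq_len(d[3]), function(r) volume$data[, , r, iy])
    if (register) {
      reg <- register_repeats(frames, max_shift = max_shift)
      fl <- compute_flow(reg$frames)
      fl[!reg$valid_rows, ] <- 0
      shifts[, iy] <- reg$shifts
    } else {
      fl <- compute_flow(frames)
    }
    flow[, , iy] <- fl
  }
  structure(list(flow = flow, shifts = shifts, protocol = volume$protocol,
                 kernel = NULL), class = "angiogram")
}

#' Smooth an angiogram with a normalized Gaussian kernel
#'
#' Applied per en-face plane (x by y) with reflective borders, so the total
#' flow signal is preserved. Kernel size must be odd (default 3 x 3,
#' sigma = 0.8 voxels).
#'
#' @param angiogram an \code{angiogram} or a 3D \code{[z, x, y]} array.
#' @param size odd kernel size (default 3).
#' @param sigma Gaussian sigma in voxels (default 0.8).
#' @return Same type as the input, smoothed.
#' @export
smooth_angiogram <- function(angiogram, size = 3L, sigma = 0.8) {
  size <- as.integer(size)
  if (size %% 2L == 0L) stop("kernel size must be odd")
  off <- seq_len(size) - (size + 1) / 2
  k <- outer(stats::dnorm(off, sd = sigma), stats::dnorm(off, sd = sigma))
  k <- k / sum(k)
  vol <- if (inherits(angiogram, "angiogram")) angiogram$flow else angiogram
  out <- vol
  for (iz in seq_len(dim(vol)[1])) {
    out[iz, , ] <- conv2_reflect(vol[iz, , ], k)
  }
  if (inherits(angiogram, "angiogram")) {
    angiogram$flow <- out
    angiogram$kernel <- k
    angiogram
  } else out
}

as_flow_array <- function(x) {
  if (inherits(x, "angiogram")) x$flow
  else if (is.array(x) && length(dim(x)) == 3) x
  else stop("expected an angiogram or a 3D [z, x, y] array")
}

#' Maximum intensity projection over a depth range
#'
#' Per-(x, y) maximum of the volume over the half-open voxel range
#' \code{[z_from, z_to)} (1-based \code{z_from}, so the default covers the
#' full depth).
#'
#' @param x an \code{angiogram} or 3D \code{[z, x, y]} array.
#' @param z_from,z_to half-open depth range in voxels; defaults to full depth.
#' @return En-face matrix (x by y).
#' @export
mip_enface <- function(x, z_from = 1L, z_to = NULL) {
  vol <- as_flow_array(x)
  nz <- dim(vol)[1]
  z_to <- as.integer(z_to %||% (nz + 1L))
  z_from <- as.integer(z_from)
  if (z_from < 1L || z_to > nz + 1L || z_from >= z_to)
    stop(sprintf("empty or out-of-range depth range [%d, %d)", z_from, z_to))
  zs <- z_from:(z_to - 1L)
  out <- vol[zs[1], , ]
  for (iz in zs[-1]) out <- pmax(out, vol[iz, , ])
  matrix(out, dim(vol)[2], dim(vol)[3])
}

#' Depth-encoded maximum intensity projection
#'
#' En-face maximum over depth together with the depth (voxels and um) at
#' which it occurs; ties resolve to the shallowest depth. Blood vessels can
#' then be color-coded by depth-of-maximum. An all-zero column keeps depth 1
#' and is reported in \code{flat}.
#'
#' @param x an \code{angiogram} or 3D \code{[z, x, y]} array.
#' @param axial_pitch_um voxel pitch used for the um-scaled depth map;
#'   taken from the angiogram protocol when available.
#' @return List of class \code{depth_mip}: \code{value} (x by y),
#'   \code{depth_vox} (1-based argmax), \code{depth_um}, \code{flat}
#'   (logical, columns with no signal).
#' @export
depth_encoded_mip <- function(x, axial_pitch_um = NULL) {
  vol <- as_flow_array(x)
  if (is.null(axial_pitch_um) && inherits(x, "angiogram"))
    axial_pitch_um <- x$protocol$axial_pitch_um
  d <- dim(vol)
  value <- matrix(vol[1, , ], d[2], d[3])
  depth <- matrix(1L, d[2], d[3])
  if (d[1] > 1) for (iz in 2:d[1]) {
    sl <- matrix(vol[iz, , ], d[2], d[3])
    upd <- sl > value          # strict: ties keep the shallower depth
    value[upd] <- sl[upd]
    depth[upd] <- iz
  }
  flat <- value == 0
  structure(list(value = value, depth_vox = depth,
                 depth_um = if (!is.null(axial_pitch_um)) (depth - 1L) * axial_pitch_um else NULL,
                 flat = flat), class = "depth_mip")
}
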