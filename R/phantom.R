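# Synthetic layered skin phantom with voxel-level ground truth.
#
# The phantom realizes the two contrast mechanisms the pipeline exploits:
# lymphatic lumens are low-scattering (dark) tubes in the dermis, and blood
# vessels carry dynamic speckle, i.e. their complex OCT signal decorrelates
# between repeated B-frames while static tissue stays identical up to the
# noise floor. Speckle is modelled as a fully developed complex
# circular-Gaussian field (Rayleigh amplitude), scaled by a layer/lumen
# reflectivity map and attenuated as exp(-mu * depth) in amplitude
# (exp(-2 mu * depth) in intensity) measured from the local tissue surface.

#' Define a tube (vessel) for the skin phantom
#'
#' A tube is a polyline centerline in physical micrometre coordinates
#' \code{(z, x, y)} (z measured down from the first voxel plane) with a
#' radius. Distance to the centerline is Euclidean in micrometres, so tubes
#' keep a circular cross-section under anisotropic voxel pitch.
#'
#' @param points numeric matrix with columns (z_um, x_um, y_um), one row per
#'   polyline vertex (>= 2 rows).
#' @param radius_um tube radius in micrometres (> 0).
#' @param scale for lymph tubes: amplitude scale of the lumen relative to
#'   dermis, in [0, 1) — lymph fluid scatters weakly, default 0.1. For blood
#'   tubes: interpreted as the decorrelation fraction in (0, 1], default 1
#'   (fully fresh speckle every repeat).
#' @return An object of class \code{phantom_tube}.
#' @export
phantom_tube <- function(points, radius_um, scale) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2, radius_um > 0)
  structure(list(points = points, radius_um = radius_um, scale = scale),
            class = "phantom_tube")
}

default_lymph_tubes <- function(nx_um, ny_um, edj_um) {
  # One lumen per dermal slab, spanning the slow axis (inset by one radius so
  # the whole tube sits inside the grid); deeper dermal lymphatics are
  # larger, as in skin.
  list(
    phantom_tube(rbind(c(edj_um + 100, 0.25 * nx_um, 60),
                       c(edj_um + 100, 0.25 * nx_um, ny_um - 60)), 60, 0.1),
    phantom_tube(rbind(c(edj_um + 300, 0.50 * nx_um, 70),
                       c(edj_um + 300, 0.50 * nx_um, ny_um - 70)), 70, 0.1),
    phantom_tube(rbind(c(edj_um + 500, 0.75 * nx_um, 70),
                       c(edj_um + 500, 0.75 * nx_um, ny_um - 70)), 70, 0.1)
  )
}

default_blood_tubes <- function(nx_um, ny_um, edj_um) {
  list(
    phantom_tube(rbind(c(edj_um + 200, 40, 0.30 * ny_um),
                       c(edj_um + 200, nx_um - 40, 0.30 * ny_um)), 40, 1.0),
    phantom_tube(rbind(c(edj_um + 380, 40, 0.70 * ny_um),
                       c(edj_um + 380, nx_um - 40, 0.70 * ny_um)), 40, 1.0)
  )
}

#' Specification of a synthetic skin-OCT phantom
#'
#' Defaults describe a 2.56 mm x 2.56 mm x 1 mm block of skin sampled at
#' 8 um axial / 20 um lateral pitch with 8 repeated B-frames per location:
#' air above an (optionally wavy) surface, a brighter epidermis of 120 um,
#' dermis below, three lymphatic lumens (one per 200-um dermal slab) and two
#' decorrelating blood vessels. The noise floor sigma = 0.02 per quadrature
#' corresponds to roughly -34 dB relative to the unattenuated dermis signal,
#' a high-SNR acquisition.
#'
#' @param nz,nx,ny grid size in voxels (z = depth, x = fast, y = slow axis).
#' @param axial_pitch_um,lateral_pitch_um voxel pitch (um).
#' @param dermis_amplitude mean dermis backscatter amplitude (a.u.).
#' @param epidermis_multiplier epidermis amplitude relative to dermis (> 1
#'   makes the epidermis brighter; 1 removes the layer contrast).
#' @param epidermis_thickness_um epidermis thickness (um).
#' @param mu_per_mm attenuation coefficient mu (1/mm), applied to amplitude as
#'   exp(-mu d) with d the depth below the local surface.
#' @param lymph_tubes,blood_tubes lists of \code{\link{phantom_tube}}; pass
#'   \code{list()} for none. \code{NULL} selects the defaults above.
#' @param n_repeats repeated B-frames per y location (>= 2 when blood tubes
#'   are present).
#' @param bulk_shifts_vox integer axial bulk-motion shift per repeat (length
#'   \code{n_repeats}, recycled over y locations; positive = deeper), or a
#'   \code{n_repeats} x \code{ny} matrix for per-frame shifts.
#' @param surface_depth_um mean tissue surface depth below the first voxel
#'   plane (um).
#' @param topography_amplitude_um,topography_period_um sinusoidal surface
#'   height variation (um); amplitude 0 gives a flat surface.
#' @param noise_sigma additive complex noise, standard deviation per
#'   quadrature (a.u.).
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(nz = 128L, nx = 128L, ny = 128L,
                         axial_pitch_um = 8, lateral_pitch_um = 20,
                         dermis_amplitude = 1,
                         epidermis_multiplier = 2,
                         epidermis_thickness_um = 120,
                         mu_per_mm = 1.5,
                         lymph_tubes = NULL, blood_tubes = NULL,
                         n_repeats = 8L,
                         bulk_shifts_vox = NULL,
                         surface_depth_um = 128,
                         topography_amplitude_um = 16,
                         topography_period_um = 1280,
                         noise_sigma = 0.02) {
  nz <- as.integer(nz); nx <- as.integer(nx); ny <- as.integer(ny)
  n_repeats <- as.integer(n_repeats)
  stopifnot(nz >= 4, nx >= 1, ny >= 1, n_repeats >= 1,
            axial_pitch_um > 0, lateral_pitch_um > 0,
            dermis_amplitude > 0, epidermis_multiplier > 0,
            epidermis_thickness_um >= 0, mu_per_mm >= 0,
            surface_depth_um >= 0, topography_amplitude_um >= 0,
            noise_sigma >= 0)
  edj_um <- surface_depth_um + epidermis_thickness_um
  nx_um <- (nx - 1) * lateral_pitch_um
  ny_um <- (ny - 1) * lateral_pitch_um
  if (is.null(lymph_tubes)) lymph_tubes <- default_lymph_tubes(nx_um, ny_um, edj_um)
  if (is.null(blood_tubes)) blood_tubes <- default_blood_tubes(nx_um, ny_um, edj_um)
  if (is.null(bulk_shifts_vox)) bulk_shifts_vox <- integer(n_repeats)
  spec <- structure(list(
    nz = nz, nx = nx, ny = ny,
    axial_pitch_um = axial_pitch_um, lateral_pitch_um = lateral_pitch_um,
    dermis_amplitude = dermis_amplitude,
    epidermis_multiplier = epidermis_multiplier,
    epidermis_thickness_um = epidermis_thickness_um,
    mu_per_mm = mu_per_mm,
    lymph_tubes = lymph_tubes, blood_tubes = blood_tubes,
    n_repeats = n_repeats, bulk_shifts_vox = bulk_shifts_vox,
    surface_depth_um = surface_depth_um,
    topography_amplitude_um = topography_amplitude_um,
    topography_period_um = topography_period_um,
    noise_sigma = noise_sigma
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  zmax <- (spec$nz - 1) * spec$axial_pitch_um
  xmax <- (spec$nx - 1) * spec$lateral_pitch_um
  ymax <- (spec$ny - 1) * spec$lateral_pitch_um
  check_tube <- function(t, kind, i) {
    if (!inherits(t, "phantom_tube")) stop(kind, " tube ", i, " is not a phantom_tube")
    if (t$radius_um <= 0) stop(kind, " tube ", i, ": radius must be > 0")
    if (kind == "lymph" && (t$scale < 0 || t$scale >= 1))
      stop("lymph tube ", i, ": amplitude scale must be in [0, 1)")
    if (kind == "blood" && (t$scale <= 0 || t$scale > 1))
      stop("blood tube ", i, ": decorrelation fraction must be in (0, 1]")
    p <- t$points; r <- t$radius_um
    if (min(p[, 1]) - r < 0 || max(p[, 1]) + r > zmax ||
        min(p[, 2]) - r < 0 || max(p[, 2]) + r > xmax ||
        min(p[, 3]) - r < 0 || max(p[, 3]) + r > ymax)
      stop(sprintf("%s tube %d extends outside the grid (z 0..%g, x 0..%g, y 0..%g um)",
                   kind, i, zmax, xmax, ymax))
    invisible(TRUE)
  }
  for (i in seq_along(spec$lymph_tubes)) check_tube(spec$lymph_tubes[[i]], "lymph", i)
  for (i in seq_along(spec$blood_tubes)) check_tube(spec$blood_tubes[[i]], "blood", i)
  if (length(spec$blood_tubes) > 0 && spec$n_repeats < 2)
    stop("n_repeats must be >= 2 when blood tubes are present")
  sh <- spec$bulk_shifts_vox
  if (is.matrix(sh)) {
    if (nrow(sh) != spec$n_repeats || ncol(sh) != spec$ny)
      stop("bulk_shifts_vox matrix must be n_repeats x ny")
  } else if (length(sh) != spec$n_repeats) {
    stop("bulk_shifts_vox must have length n_repeats (or be a n_repeats x ny matrix)")
  }
  if (any(sh != round(sh))) stop("bulk shifts must be integer voxels")
  invisible(spec)
}

# Boolean voxel mask of a tube on the phantom grid, via exact point-to-segment
# distance in micrometres, evaluated on the tube's bounding box only.
tube_mask <- function(tube, spec) {
  dz <- spec$axial_pitch_um; dl <- spec$lateral_pitch_um
  mask <- array(FALSE, c(spec$nz, spec$nx, spec$ny))
  r <- tube$radius_um
  p <- tube$points
  for (s in seq_len(nrow(p) - 1)) {
    a <- p[s, ]; b <- p[s + 1, ]
    lo <- pmin(a, b) - r; hi <- pmax(a, b) + r
    iz <- max(1L, floor(lo[1] / dz) + 1L):min(spec$nz, ceiling(hi[1] / dz) + 1L)
    ix <- max(1L, floor(lo[2] / dl) + 1L):min(spec$nx, ceiling(hi[2] / dl) + 1L)
    iy <- max(1L, floor(lo[3] / dl) + 1L):min(spec$ny, ceiling(hi[3] / dl) + 1L)
    cz <- (iz - 1) * dz; cx <- (ix - 1) * dl; cy <- (iy - 1) * dl
    gz <- array(cz, c(length(iz), length(ix), length(iy)))
    gx <- aperm(array(cx, c(length(ix), length(iz), length(iy))), c(2, 1, 3))
    gy <- aperm(array(cy, c(length(iy), length(iz), length(ix))), c(2, 3, 1))
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- (gz - a[1])^2 + (gx - a[2])^2 + (gy - a[3])^2
    } else {
      t <- ((gz - a[1]) * ab[1] + (gx - a[2]) * ab[2] + (gy - a[3]) * ab[3]) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (gz - (a[1] + t * ab[1]))^2 +
            (gx - (a[2] + t * ab[2]))^2 +
            (gy - (a[3] + t * ab[3]))^2
    }
    sub <- mask[iz, ix, iy, drop = FALSE]
    mask[iz, ix, iy] <- sub | (d2 <= r^2)
  }
  mask
}

# Analytic centerline length (um) of a tube.
tube_length_um <- function(tube) {
  p <- tube$points
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Analytic lymph-tube volume fraction of a phantom
#'
#' The voxel mask of a tube contains the voxel centers within one radius of
#' the centerline, i.e. a capsule: cylinder pi r^2 L plus spherical end caps
#' (4/3) pi r^3. The ground-truth mask fraction agrees with this capsule
#' volume over the grid volume within voxelization error.
#'
#' @param spec a \code{phantom_spec}.
#' @return Expected fraction of grid voxels inside lymph tubes.
#' @export
analytic_lymph_fraction <- function(spec) {
  vol_um3 <- sum(vapply(spec$lymph_tubes, function(t)
    pi * t$radius_um^2 * tube_length_um(t) + (4 / 3) * pi * t$radius_um^3, 0))
  grid_um3 <- (spec$nz * spec$axial_pitch_um) *
    (spec$nx * spec$lateral_pitch_um) * (spec$ny * spec$lateral_pitch_um)
  vol_um3 / grid_um3
}

complex_gaussian <- function(n) {
  complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) / sqrt(2)
}

#' Generate a synthetic skin-OCT volume with ground truth
#'
#' Draws a fully developed speckle realization of the phantom described by
#' \code{spec}: a static complex circular-Gaussian field scaled by the
#' layer/lumen reflectivity map and attenuated from the local surface, copied
#' to every repeat; voxels inside blood tubes are re-randomized each repeat
#' (mixed by the decorrelation fraction), so only they decorrelate; per-frame
#' integer bulk shifts are applied; complex noise is added last. The same
#' \code{(spec, seed)} pair reproduces the volume bit-for-bit.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param seed integer RNG seed.
#' @return List with \code{volume} (a \code{\link{bscan_volume}}, complex
#'   mode) and \code{truth}: \code{lymph_mask}, \code{blood_mask} (logical
#'   \code{[z, x, y]}, disjoint), \code{surface_vox}, \code{edj_vox}
#'   (1-based first-voxel index maps, x by y) and \code{bulk_shifts_vox}
#'   (n_repeats by ny matrix as applied).
#' @export
generate_phantom <- function(spec, seed = 1L) {
  validate_phantom_spec(spec)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  nz <- spec$nz; nx <- spec$nx; ny <- spec$ny; R <- spec$n_repeats
  dz <- spec$axial_pitch_um; dl <- spec$lateral_pitch_um

  # Surface and EDJ maps (1-based index of the first voxel of each layer).
  x_um <- (seq_len(nx) - 1) * dl
  y_um <- (seq_len(ny) - 1) * dl
  s_um <- spec$surface_depth_um + spec$topography_amplitude_um *
    outer(sin(2 * pi * x_um / spec$topography_period_um),
          cos(2 * pi * y_um / spec$topography_period_um))
  surface_vox <- ceiling(s_um / dz - 1e-9) + 1L
  edj_vox <- ceiling((s_um + spec$epidermis_thickness_um) / dz - 1e-9) + 1L
  surface_vox <- pmin(pmax(surface_vox, 1L), nz)
  edj_vox <- pmin(pmax(edj_vox, surface_vox), nz)

  # Reflectivity amplitude map from the integer layer maps.
  zidx <- array(seq_len(nz), c(nz, nx, ny))
  surf3 <- aperm(array(surface_vox, c(nx, ny, nz)), c(3, 1, 2))
  edj3 <- aperm(array(edj_vox, c(nx, ny, nz)), c(3, 1, 2))
  amp <- array(0, c(nz, nx, ny))
  amp[zidx >= surf3 & zidx < edj3] <- spec$dermis_amplitude * spec$epidermis_multiplier
  amp[zidx >= edj3] <- spec$dermis_amplitude

  lymph_masks <- lapply(spec$lymph_tubes, tube_mask, spec = spec)
  blood_mask <- array(FALSE, c(nz, nx, ny))
  for (t in spec$blood_tubes) blood_mask <- blood_mask | tube_mask(t, spec)
  lymph_mask <- array(FALSE, c(nz, nx, ny))
  for (m in lymph_masks) lymph_mask <- lymph_mask | m
  lymph_mask <- lymph_mask & !blood_mask   # blood wins at tube crossings
  for (i in seq_along(lymph_masks)) {
    m <- lymph_masks[[i]] & !blood_mask
    amp[m] <- amp[m] * spec$lymph_tubes[[i]]$scale
  }

  # Round-trip attenuation from the local surface: amplitude exp(-mu d).
  depth_um <- pmax(zidx - surf3, 0) * dz
  amp <- amp * exp(-spec$mu_per_mm * depth_um / 1000)

  # Static speckle realization, shared by all repeats.
  g0 <- array(complex_gaussian(nz * nx * ny), c(nz, nx, ny)) * amp

  blood_frac <- array(0, c(nz, nx, ny))
  for (t in spec$blood_tubes) blood_frac[tube_mask(t, spec)] <- t$scale
  bidx <- which(blood_mask)
  keep <- sqrt(1 - blood_frac[bidx])
  mix <- sqrt(blood_frac[bidx])

  sh <- spec$bulk_shifts_vox
  shifts <- if (is.matrix(sh)) sh else matrix(as.integer(sh), R, ny)
  storage.mode(shifts) <- "integer"

  data <- array(complex(real = 0), c(nz, nx, R, ny))
  for (r in seq_len(R)) {
    fr <- g0
    if (length(bidx) > 0) {
      fr[bidx] <- keep * g0[bidx] + mix * complex_gaussian(length(bidx)) * amp[bidx]
    }
    for (iy in seq_len(ny)) {
      s <- shifts[r, iy]
      frame <- fr[, , iy]
      if (s != 0) frame <- shift_axial(frame, s)
      data[, , r, iy] <- frame
    }
    if (spec$noise_sigma > 0) {
      data[, , r, ] <- data[, , r, ] +
        spec$noise_sigma * sqrt(2) * complex_gaussian(nz * nx * ny)
    }
  }

  proto <- scan_protocol(
    fov_x_mm = nx * dl / 1000, fov_y_mm = ny * dl / 1000,
    n_alines = nx, n_y = ny, n_repeats = R,
    frame_rate_hz = 100, axial_pitch_um = dz,
    axial_range_mm = nz * dz / 1000)
  volume <- bscan_volume(data, proto, mode = "complex", source = "phantom")
  truth <- list(lymph_mask = lymph_mask, blood_mask = blood_mask,
                surface_vox = surface_vox, edj_vox = edj_vox,
                bulk_shifts_vox = shifts)
  list(volume = volume, truth = truth)
}

# Shift a (z, x) frame axially by s voxels (positive = content moves deeper),
# zero-filling vacated rows.
shift_axial <- function(frame, s) {
  nz <- nrow(frame)
  out <- frame
  out[] <- 0
  if (s >= nz || s <= -nz) return(out)
  if (s >= 0) out[(1 + s):nz, ] <- frame[1:(nz - s), ]
  else out[1:(nz + s), ] <- frame[(1 - s):nz, ]
  out
}
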