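# OCT-based lymphangiography: lymphatic lumens are low-scattering (dark)
# regions in the dermis. The chain is: attenuation compensation (flattens
# depth-dependent signal loss and sharpens the epidermis/dermis contrast),
# surface + epidermal-dermal junction (EDJ) segmentation, flattening to the
# EDJ, per-slice en-face histogram equalization, sorted minimum intensity
# projection (sMIP) over dermal slabs, and thresholding into a lymph mask.

#' Attenuation compensation of a structural volume
#'
#' Per A-line, each intensity is divided by twice the remaining tail energy
#' (inclusive of the pixel itself), after raising intensities to an exponent
#' \code{n} for contrast:
#' \deqn{A(z) = I(z)^n / (2 \sum_{u \ge z} I(u)^n)}
#' Output lies in [0, 0.5]; the deepest nonzero pixel of every A-line maps to
#' exactly 0.5. All-zero A-lines return zeros and are flagged.
#'
#' @param volume 3D nonnegative intensity array \code{[z, x, y]} (use
#'   \code{\link{structural_amplitude}} squared, or any monotone intensity).
#' @param n exponent applied to intensities before compensation (default 2).
#' @return List of class \code{compensated_volume}: \code{data} (same dims,
#'   in [0, 0.5]), \code{flagged} (logical x by y, all-zero A-lines), \code{n}.
#' @export
compensate_attenuation <- function(volume, n = 2) {
  stopifnot(is.array(volume), length(dim(volume)) == 3)
  if (min(volume) < 0) stop("intensities must be nonnegative")
  d <- dim(volume)
  p <- volume^n
  m <- matrix(p, d[1], d[2] * d[3])
  # inclusive tail sum: reverse cumulative sum down each A-line
  tail <- apply(m, 2, function(v) rev(cumsum(rev(v))))
  out <- matrix(0, d[1], d[2] * d[3])
  nz_tail <- tail > 0
  out[nz_tail] <- m[nz_tail] / (2 * tail[nz_tail])
  flagged <- matrix(colSums(m) == 0, d[2], d[3])
  structure(list(data = array(out, d), flagged = flagged, n = n),
            class = "compensated_volume")
}

#' Detect the tissue surface
#'
#' Per (x, y) column, the shallowest depth where the axially smoothed
#' amplitude exceeds a noise threshold (median + k * MAD of the noise region,
#' taken from the top \code{noise_rows} voxel planes across the volume). The
#' resulting map is median-filtered laterally (3 x 3). Columns that never
#' exceed the threshold are flagged and filled from their neighbours.
#'
#' @param amplitude 3D amplitude array \code{[z, x, y]}.
#' @param k MAD multiplier for the threshold (default 6).
#' @param noise_rows number of top planes assumed to be above the tissue
#'   (default 8).
#' @param axial_window odd moving-average window before thresholding
#'   (default 3).
#' @return List of class \code{surface_map}: \code{surface_vox} (x by y,
#'   1-based), \code{flagged} (logical x by y), \code{threshold}.
#' @export
detect_surface <- function(amplitude, k = 6, noise_rows = 8L, axial_window = 3L) {
  stopifnot(is.array(amplitude), length(dim(amplitude)) == 3)
  d <- dim(amplitude)
  noise_rows <- min(as.integer(noise_rows), d[1])
  noise <- amplitude[seq_len(noise_rows), , , drop = FALSE]
  thr <- stats::median(noise) + k * stats::mad(noise)
  if (thr <= 0) thr <- .Machine$double.eps
  m <- matrix(amplitude, d[1], d[2] * d[3])
  sm <- axial_smooth(m, axial_window)
  above <- sm > thr
  h <- axial_window %/% 2
  first <- vapply(seq_len(ncol(m)), function(j) {
    w <- which(above[, j])
    if (!length(w)) return(NA_integer_)
    f <- w[1]
    # the centered smoothing window biases the crossing shallow by up to h
    # voxels; snap to the first raw-amplitude crossing nearby
    lo <- max(1L, f - h); hi <- min(d[1], f + h)
    raw <- which(m[lo:hi, j] > thr)
    as.integer(if (length(raw)) lo + raw[1] - 1L else f)
  }, 0L)
  surf <- matrix(as.numeric(first), d[2], d[3])
  flagged <- is.na(surf)
  if (any(flagged)) {
    if (all(flagged)) {
      warning("no column exceeds the surface threshold; all columns flagged")
      surf[] <- 1
    } else {
      surf <- fill_flagged(surf, flagged)
    }
  }
  if (d[2] >= 3 && d[3] >= 3) surf <- median_filter3(surf)
  surf <- pmin(pmax(round(surf), 1), d[1])
  structure(list(surface_vox = surf, flagged = flagged, threshold = thr),
            class = "surface_map")
}

#' Segment the epidermal-dermal junction (EDJ)
#'
#' Per column of the compensated volume, the EDJ is located with a
#' step-matched filter: the depth z maximizing the contrast between the mean
#' intensity just above (\code{edge_halfwidth} voxels, the bright epidermis)
#' and just below (dermis), searched over
#' \code{[surface + window_um[1], surface + window_um[2]]}. Each en-face
#' plane is 3 x 3 box-averaged first to tame speckle. Columns whose best
#' step contrast is small relative to the local intensity (no real junction,
#' e.g. no epidermis brightness contrast) are flagged and filled from
#' neighbours; the map is median-filtered laterally and clamped to
#' >= surface.
#'
#' @param compensated a \code{compensated_volume} (or 3D array).
#' @param surface a \code{surface_map} (or an x-by-y voxel map).
#' @param axial_pitch_um axial voxel pitch (um).
#' @param window_um search window below the surface, default c(40, 300) um.
#' @param edge_halfwidth voxels averaged on each side of the candidate edge
#'   (default 3).
#' @param min_peak flag columns whose best step contrast does not exceed
#'   \code{min_peak} times the median absolute step response in their search
#'   window — a real junction produces a response far above the speckle
#'   background, a contrast-free profile does not (default 4).
#' @return List of class \code{edj_map}: \code{edj_vox} (x by y),
#'   \code{flagged}.
#' @export
segment_edj <- function(compensated, surface, axial_pitch_um,
                        window_um = c(40, 300), edge_halfwidth = 3L,
                        min_peak = 4) {
  vol <- if (inherits(compensated, "compensated_volume")) compensated$data else compensated
  surf <- if (inherits(surface, "surface_map")) surface$surface_vox else surface
  d <- dim(vol)
  w0 <- round(window_um[1] / axial_pitch_um)
  w1 <- round(window_um[2] / axial_pitch_um)
  e <- as.integer(edge_halfwidth)
  if (w1 >= d[1]) stop("EDJ search window exceeds the volume depth")
  # lateral 3x3 box average per en-face plane to suppress speckle
  sm3 <- vol
  if (d[2] >= 3 && d[3] >= 3) {
    box <- matrix(1 / 9, 3, 3)
    for (iz in seq_len(d[1])) sm3[iz, , ] <- conv2_reflect(vol[iz, , ], box)
  }
  m <- matrix(sm3, d[1], d[2] * d[3])
  cs <- rbind(0, apply(m, 2, cumsum))
  # step contrast at z: mean over [z-e, z-1] minus mean over [z, z+e-1]
  zs <- (e + 1):(d[1] - e + 1)
  above <- (cs[zs, , drop = FALSE] - cs[zs - e, , drop = FALSE]) / e
  below <- (cs[zs + e, , drop = FALSE] - cs[zs, , drop = FALSE]) / e
  score <- above - below
  edj <- matrix(NA_real_, d[2], d[3])
  strength <- matrix(0, d[2], d[3])
  noise_floor <- matrix(Inf, d[2], d[3])
  for (j in seq_len(d[2] * d[3])) {
    lo <- max(surf[j] + w0, zs[1])
    hi <- min(surf[j] + w1, zs[length(zs)])
    if (lo >= hi) next
    ii <- (lo - zs[1] + 1):(hi - zs[1] + 1)
    g <- score[ii, j]
    i <- which.max(g)
    edj[j] <- lo + i - 1
    strength[j] <- g[i]
    noise_floor[j] <- stats::median(abs(g))
  }
  flagged <- is.na(edj) |
    strength < min_peak * pmax(noise_floor, .Machine$double.eps)
  flagged[is.na(flagged)] <- TRUE
  if (all(flagged)) {
    warning("no epidermis/dermis contrast found; all EDJ columns flagged")
    edj[] <- surf
  } else if (any(flagged)) {
    edj <- fill_flagged(edj, flagged)
  }
  if (d[2] >= 3 && d[3] >= 3) edj <- median_filter3(edj)
  edj <- pmin(pmax(round(edj), surf), d[1])
  structure(list(edj_vox = edj, flagged = flagged), class = "edj_map")
}

#' Flatten a volume to a reference depth map
#'
#' Shifts every A-line so the reference (typically the EDJ) sits at a
#' constant index \code{target} (default: the maximum of the map, so no
#' content is pushed off the top). Vacated voxels are marked invalid.
#'
#' @param volume 3D array \code{[z, x, y]}.
#' @param reference x-by-y voxel map (1-based), e.g. \code{edj_vox}.
#' @param target index the reference is moved to (default \code{max(reference)}).
#' @return List of class \code{flat_volume}: \code{data}, \code{valid}
#'   (logical, same dims), \code{target}, \code{reference}.
#' @export
flatten_volume <- function(volume, reference, target = NULL) {
  stopifnot(is.array(volume), length(dim(volume)) == 3)
  d <- dim(volume)
  reference <- round(reference)
  if (any(reference < 1) || any(reference > d[1]))
    stop("reference map outside [1, nz]")
  target <- as.integer(target %||% max(reference))
  data <- array(0, d)
  valid <- array(FALSE, d)
  for (j in seq_len(d[2] * d[3])) {
    jx <- (j - 1) %% d[2] + 1; jy <- (j - 1) %/% d[2] + 1
    s <- target - reference[jx, jy]
    src <- seq_len(d[1]) - s
    ok <- src >= 1 & src <= d[1]
    data[ok, jx, jy] <- volume[src[ok], jx, jy]
    valid[ok, jx, jy] <- TRUE
  }
  structure(list(data = data, valid = valid, target = target,
                 reference = reference), class = "flat_volume")
}

#' Undo \code{\link{flatten_volume}}
#'
#' @param flat a \code{flat_volume}.
#' @return List \code{data}, \code{valid} in the original geometry.
#' @export
unflatten_volume <- function(flat) {
  stopifnot(inherits(flat, "flat_volume"))
  d <- dim(flat$data)
  data <- array(0, d); valid <- array(FALSE, d)
  for (j in seq_len(d[2] * d[3])) {
    jx <- (j - 1) %% d[2] + 1; jy <- (j - 1) %/% d[2] + 1
    s <- flat$reference[jx, jy] - flat$target
    src <- seq_len(d[1]) - s
    ok <- src >= 1 & src <= d[1]
    data[ok, jx, jy] <- flat$data[src[ok], jx, jy]
    valid[ok, jx, jy] <- flat$valid[src[ok], jx, jy]
  }
  list(data = data, valid = valid)
}

#' Histogram-equalize an en-face slice
#'
#' Global rank equalization over the valid pixels: each value is mapped to
#' \code{(rank - 0.5) / N}, i.e. the empirical CDF, giving a uniform [0, 1]
#' output while preserving rank order (ties share the average rank). Invalid
#' pixels are returned as NA. A constant slice returns 0.5 everywhere and is
#' flagged.
#'
#' @param slice numeric matrix.
#' @param valid logical matrix of pixels to include (default all).
#' @return List of class \code{equalized_slice}: \code{data}, \code{flagged}
#'   (TRUE when the slice was constant).
#' @export
enface_equalize <- function(slice, valid = NULL) {
  stopifnot(is.matrix(slice))
  valid <- valid %||% matrix(TRUE, nrow(slice), ncol(slice))
  out <- matrix(NA_real_, nrow(slice), ncol(slice))
  v <- slice[valid]
  if (length(v) == 0) return(structure(list(data = out, flagged = TRUE),
                                       class = "equalized_slice"))
  if (max(v) == min(v)) {
    out[valid] <- 0.5
    return(structure(list(data = out, flagged = TRUE), class = "equalized_slice"))
  }
  out[valid] <- (rank(v, ties.method = "average") - 0.5) / length(v)
  structure(list(data = out, flagged = FALSE), class = "equalized_slice")
}

#' Sorted minimum intensity projection (sMIP) over a dermal slab
#'
#' For each (x, y) column, the k smallest valid intensities within the slab
#' \code{[d1, d2)} micrometres below the flattened EDJ are averaged. Dark
#' lymphatic lumens survive this projection while bright speckle is
#' suppressed. \code{k = 1} is a plain minimum projection; \code{k} equal to
#' the slab thickness is a mean projection.
#'
#' @param flat a \code{flat_volume} flattened to the EDJ (or a list with
#'   \code{data}, \code{valid}, \code{target}).
#' @param slab_um numeric c(d1, d2), half-open slab below the EDJ in um.
#' @param axial_pitch_um axial voxel pitch (um).
#' @param k number of smallest values averaged; \code{NULL} selects 20\% of
#'   the slab thickness in voxels (at least 1) — large enough that the
#'   average of the k smallest speckle samples concentrates away from zero,
#'   yet below the fraction of the slab a typical dermal lumen (diameter
#'   >= 100 um against 200-um slabs) fills. \code{equalize} applies
#'   per-slice rank equalization within the slab before projecting.
#' @param equalize logical, default TRUE.
#' @return List of class \code{lymph_enface}: \code{data} (x by y, NA where
#'   no valid voxel), \code{k}, \code{slab_um}, \code{flagged} (pixels with
#'   an empty valid slab).
#' @export
smip <- function(flat, slab_um, axial_pitch_um, k = NULL, equalize = TRUE) {
  stopifnot(length(slab_um) == 2, slab_um[1] >= 0, slab_um[1] < slab_um[2])
  d <- dim(flat$data)
  z0 <- flat$target + floor(slab_um[1] / axial_pitch_um)
  z1 <- flat$target + ceiling(slab_um[2] / axial_pitch_um) - 1L
  z0 <- max(z0, 1L); z1 <- min(z1, d[1])
  if (z0 > z1) stop("slab lies outside the volume depth")
  nzs <- z1 - z0 + 1L
  if (is.null(k)) k <- max(1L, round(0.2 * nzs))
  k <- as.integer(k)
  if (k < 1L || k > nzs)
    stop(sprintf("k = %d out of range for a %d-voxel slab", k, nzs))
  slab <- flat$data[z0:z1, , , drop = FALSE]
  vmask <- flat$valid[z0:z1, , , drop = FALSE]
  if (equalize) {
    for (iz in seq_len(nzs)) {
      eq <- enface_equalize(matrix(slab[iz, , ], d[2], d[3]),
                            matrix(vmask[iz, , ], d[2], d[3]))
      slab[iz, , ] <- ifelse(is.na(eq$data), 0, eq$data)
    }
  }
  out <- matrix(NA_real_, d[2], d[3])
  flagged <- matrix(FALSE, d[2], d[3])
  sm <- matrix(slab, nzs, d[2] * d[3])
  vm <- matrix(vmask, nzs, d[2] * d[3])
  for (j in seq_len(d[2] * d[3])) {
    v <- sm[vm[, j], j]
    if (length(v) == 0) { flagged[j] <- TRUE; next }
    kk <- min(k, length(v))
    # exact reductions at the extremes: k = 1 is a min projection, k = slab
    # thickness a mean projection
    out[j] <- if (kk == 1L) min(v)
      else if (kk == length(v)) mean(v)
      else mean(sort.int(v, partial = kk)[seq_len(kk)])
  }
  structure(list(data = out, k = k, slab_um = slab_um, flagged = flagged),
            class = "lymph_enface")
}

#' Extract a lymphatic-vessel mask from a sMIP map
#'
#' Pixels darker than a threshold become vessel candidates; connected
#' components smaller than \code{min_size} pixels are dropped, and an
#' optional elongation filter removes compact (edema-like) blobs whose
#' major-axis length over equivalent diameter falls below
#' \code{elongation_ratio} — lymphatic vessels are elongated, edema patches
#' are not.
#'
#' The default threshold is Otsu computed on the log-intensity of the map.
#' Lumen-to-tissue contrast is multiplicative and the vessel class occupies
#' only a few percent of the field; under that class imbalance Otsu on the
#' linear histogram splits the dominant tissue mode, whereas in the log
#' domain the lumen mode is far enough from the tissue mode that the
#' between-class criterion locks onto the true valley. A fixed-percentile
#' rule is available as an alternative (note it pins the detected density,
#' so it is unsuitable for longitudinal density monitoring).
#'
#' @param map a \code{lymph_enface} (or numeric matrix).
#' @param method \code{"otsu"} (log-domain) or \code{"percentile"}.
#' @param percentile used when \code{method = "percentile"} (default 0.1:
#'   darkest 10\% of pixels).
#' @param min_size minimum component size in pixels (default 10).
#' @param elongation_filter drop low-elongation components (default FALSE).
#' @param elongation_ratio threshold on major axis / equivalent diameter
#'   (default 1.8).
#' @return List of class \code{lymph_mask}: \code{mask} (logical x by y),
#'   \code{threshold} (intensity units), \code{method}, \code{min_size}.
#' @export
extract_lymph_mask <- function(map, method = c("otsu", "percentile"),
                               percentile = 0.1, min_size = 10L,
                               elongation_filter = FALSE,
                               elongation_ratio = 1.8) {
  method <- match.arg(method)
  img <- if (inherits(map, "lymph_enface")) map$data else map
  stopifnot(is.matrix(img))
  valid <- is.finite(img)
  v <- img[valid]
  if (length(v) == 0 || max(v) == min(v)) {
    warning("constant or empty sMIP map; returning empty mask")
    return(structure(list(mask = matrix(FALSE, nrow(img), ncol(img)),
                          threshold = NA_real_, method = method,
                          min_size = min_size), class = "lymph_mask"))
  }
  thr <- if (method == "otsu") {
    eps <- max(v) * 1e-4                 # floor so empty-lumen zeros stay finite
    lg <- log(pmax(img, eps))
    lv <- lg[valid]
    scaled <- (lg - min(lv)) / (max(lv) - min(lv))
    scaled[!valid] <- 1                  # invalid pixels pushed to the bright side
    t01 <- EBImage::otsu(scaled, range = c(0, 1), levels = 256L)
    exp(t01 * (max(lv) - min(lv)) + min(lv))
  } else {
    stats::quantile(v, percentile, names = FALSE)
  }
  mask <- valid & img < thr
  mask <- filter_components(mask, min_size, elongation_filter, elongation_ratio)
  if (!any(mask)) warning("lymph mask is empty")
  structure(list(mask = mask, threshold = thr, method = method,
                 min_size = min_size), class = "lymph_mask")
}

# Connected-component filtering: size and (optionally) elongation, where
# elongation = major-axis length / equivalent circular diameter.
filter_components <- function(mask, min_size, elongation_filter, elongation_ratio) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes < min_size)
  if (elongation_filter) {
    feats <- EBImage::computeFeatures.moment(lab)
    if (!is.null(feats) && nrow(feats) > 0) {
      eqd <- 2 * sqrt(sizes[seq_len(nrow(feats))] / pi)
      low <- which(feats[, "m.majoraxis"] / eqd < elongation_ratio)
      drop <- union(drop, low)
    }
  }
  if (length(drop)) mask[lab %in% drop] <- FALSE
  mask
}
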