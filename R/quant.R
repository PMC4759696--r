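# Vessel-density quantification: area fraction of en-face maps classified as
# vessel, per dermal slab and over time (longitudinal monitoring).

#' Vessel area density of a binary mask
#'
#' Percentage of valid en-face pixels classified as vessel:
#' \code{100 * |mask & valid| / |valid|}. Invariant under transposition and
#' rotation of the field.
#'
#' @param mask logical matrix (or \code{lymph_mask}).
#' @param valid logical matrix of evaluable pixels (default all).
#' @return Density in percent, in [0, 100].
#' @export
vessel_area_density <- function(mask, valid = NULL) {
  if (inherits(mask, "lymph_mask")) mask <- mask$mask
  stopifnot(is.logical(mask), is.matrix(mask))
  valid <- valid %||% matrix(TRUE, nrow(mask), ncol(mask))
  if (!identical(dim(mask), dim(valid))) stop("mask and valid shapes differ")
  n_valid <- sum(valid)
  if (n_valid == 0) stop("no valid pixels to normalize by")
  100 * sum(mask & valid) / n_valid
}

#' Binarize an en-face angiogram projection
#'
#' Above-threshold pixels are vessel. Default threshold is Otsu on the
#' min-max-scaled image; \code{"percentile"} uses a fixed upper quantile.
#' A constant image yields an empty, flagged mask.
#'
#' @param img numeric matrix (e.g. a MIP of an angiogram).
#' @param method \code{"otsu"} or \code{"percentile"}.
#' @param percentile vessel fraction cutoff for the percentile rule
#'   (default 0.9: brightest 10\%).
#' @return List of class \code{vessel_mask}: \code{mask}, \code{threshold},
#'   \code{flagged}.
#' @export
binarize_angiogram <- function(img, method = c("otsu", "percentile"),
                               percentile = 0.9) {
  method <- match.arg(method)
  stopifnot(is.matrix(img))
  v <- img[is.finite(img)]
  if (length(v) == 0 || max(v) == min(v)) {
    warning("constant angiogram projection; returning empty mask")
    return(structure(list(mask = matrix(FALSE, nrow(img), ncol(img)),
                          threshold = NA_real_, flagged = TRUE),
                     class = "vessel_mask"))
  }
  thr <- if (method == "otsu") {
    scaled <- (img - min(v)) / (max(v) - min(v))
    scaled[!is.finite(scaled)] <- 0
    EBImage::otsu(scaled, range = c(0, 1), levels = 256L) * (max(v) - min(v)) + min(v)
  } else {
    stats::quantile(v, percentile, names = FALSE)
  }
  mask <- is.finite(img) & img > thr
  structure(list(mask = mask, threshold = thr, flagged = FALSE),
            class = "vessel_mask")
}

#' Dice overlap coefficient between two binary masks
#'
#' \code{2 |a & b| / (|a| + |b|)}; two empty masks agree by convention
#' (Dice 1, with an attribute \code{both_empty}).
#'
#' @param a,b logical matrices/arrays of equal shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(structure(1, both_empty = TRUE))
  2 * sum(a & b) / (na + nb)
}

#' Per-timepoint vessel density report
#'
#' @param timepoint label (e.g. "day1").
#' @param lymph_density named numeric vector, percent per slab (names are slab
#'   labels such as "0-200um").
#' @param microvascular_density scalar percent from the binarized MIP
#'   angiogram.
#' @param params list of the parameters used (recorded verbatim).
#' @return An object of class \code{density_report}.
#' @export
density_report <- function(timepoint, lymph_density,
                           microvascular_density = NA_real_, params = list()) {
  stopifnot(is.numeric(lymph_density), !is.null(names(lymph_density)))
  if (any(lymph_density < 0 | lymph_density > 100, na.rm = TRUE))
    stop("densities must be in [0, 100]")
  structure(list(timepoint = timepoint, lymph_density = lymph_density,
                 microvascular_density = microvascular_density,
                 params = params), class = "density_report")
}

#' Longitudinal density table across timepoints
#'
#' Binds per-timepoint reports into a tidy table (timepoint x slab x metric),
#' sorted by timepoint; all reports must share the same slab configuration.
#'
#' @param reports list of \code{\link{density_report}}.
#' @param path optional CSV output path.
#' @return data.frame with columns \code{timepoint}, \code{metric},
#'   \code{slab}, \code{density_percent}.
#' @export
longitudinal_report <- function(reports, path = NULL) {
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, TRUE, "density_report")))
  slabs <- names(reports[[1]]$lymph_density)
  for (r in reports) {
    if (!identical(names(r$lymph_density), slabs))
      stop("inconsistent slab configuration across reports")
  }
  rows <- lapply(reports, function(r) {
    rbind(
      data.frame(timepoint = r$timepoint, metric = "lymphatic",
                 slab = slabs, density_percent = unname(r$lymph_density),
                 stringsAsFactors = FALSE),
      if (!is.na(r$microvascular_density))
        data.frame(timepoint = r$timepoint, metric = "microvascular",
                   slab = "all", density_percent = r$microvascular_density,
                   stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$timepoint, out$metric, match(out$slab, c(slabs, "all"))), ]
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
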