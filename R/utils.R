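# Small shared numerics: padded 2D filters, argmax helpers.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Reflect-pad a matrix by `p` pixels on every side (edge mirror, no repeat of
# the border pixel beyond once; for p < dim this is standard symmetric padding).
reflect_pad <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(p, nr))), seq_len(nr), nr + 1 - rev(seq_len(min(p, nr))))
  ci <- c(rev(seq_len(min(p, nc))), seq_len(nc), nc + 1 - rev(seq_len(min(p, nc))))
  m[ri, ci, drop = FALSE]
}

# 2D convolution with a small odd kernel under reflective boundaries.
# Kernel sums are respected exactly, so a normalized kernel preserves the
# image sum up to floating error.
conv2_reflect <- function(m, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  p <- max(kr, kc) %/% 2
  mp <- reflect_pad(m, p)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      di <- i - (kr + 1) / 2
      dj <- j - (kc + 1) / 2
      out <- out + kernel[i, j] *
        mp[(p + 1 + di):(p + nrow(m) + di), (p + 1 + dj):(p + ncol(m) + dj), drop = FALSE]
    }
  }
  out
}

# 3x3 median filter on a matrix (NA-tolerant), reflective boundary.
median_filter3 <- function(m) {
  mp <- reflect_pad(m, 1)
  nr <- nrow(m); nc <- ncol(m)
  stack <- array(NA_real_, c(nr, nc, 9))
  k <- 1
  for (di in -1:1) for (dj in -1:1) {
    stack[, , k] <- mp[(2 + di):(1 + nr + di), (2 + dj):(1 + nc + dj)]
    k <- k + 1
  }
  apply(stack, c(1, 2), stats::median, na.rm = TRUE)
}

# Centered moving average along the first margin of a matrix (columns are
# A-lines); window must be odd. Edges use shrinking windows.
axial_smooth <- function(m, window = 3L) {
  stopifnot(window %% 2 == 1)
  if (window == 1L) return(m)
  h <- window %/% 2
  cs <- apply(rbind(0, m), 2, cumsum)
  n <- nrow(m)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

# Fill flagged entries of a lateral map by nearest-valid interpolation
# (iterative 3x3 neighbour mean until no NA remains).
fill_flagged <- function(m, flagged) {
  m[flagged] <- NA_real_
  while (anyNA(m)) {
    mp <- reflect_pad(m, 1)
    nr <- nrow(m); nc <- ncol(m)
    acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
    for (di in -1:1) for (dj in -1:1) {
      nb <- mp[(2 + di):(1 + nr + di), (2 + dj):(1 + nc + dj)]
      ok <- !is.na(nb)
      acc[ok] <- acc[ok] + nb[ok]
      cnt <- cnt + ok
    }
    fill <- is.na(m) & cnt > 0
    m[fill] <- acc[fill] / cnt[fill]
    if (!any(fill) && anyNA(m)) { m[is.na(m)] <- stats::median(m, na.rm = TRUE); break }
  }
  m
}
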