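# Stitch a rectangular grid of en-face tiles into one wide-field image.
# Nine 3 mm x 3 mm tiles with 0.5 mm seam overlap tile an 8 mm x 8 mm field.

#' Mosaic a grid of en-face tiles
#'
#' Tiles are placed at their nominal grid positions (tile size minus overlap
#' apart), each refined by the integer offset that maximizes the normalized
#' cross-correlation with the canvas accumulated so far, searched within
#' plus/minus the overlap. Overlap regions are blended with linear feathering
#' (distance-to-edge weights), so constant tiles stitch seamlessly.
#'
#' @param tiles list of equal-size numeric matrices, row-major grid order.
#' @param grid c(rows, cols) of the tile grid.
#' @param overlap_px seam overlap in pixels (>= 0, less than the tile size).
#' @param refine logical: run cross-correlation refinement (default TRUE).
#' @return List of class \code{mosaic}: \code{image} (stitched canvas),
#'   \code{offsets} (per-tile refined offsets, rows = tiles).
#' @export
mosaic_tiles <- function(tiles, grid, overlap_px = 0L, refine = TRUE) {
  stopifnot(is.list(tiles), length(tiles) == prod(grid))
  d <- dim(tiles[[1]])
  if (!all(vapply(tiles, function(t) identical(dim(t), d), TRUE)))
    stop("all tiles must have identical dimensions")
  overlap_px <- as.integer(overlap_px)
  if (overlap_px < 0 || overlap_px >= min(d)) stop("overlap must be in [0, tile size)")
  step <- d - overlap_px
  canvas_dim <- step * grid + overlap_px
  acc <- matrix(0, canvas_dim[1], canvas_dim[2])
  wacc <- matrix(0, canvas_dim[1], canvas_dim[2])
  # feather weight: linear ramp over the overlap margin on each tile edge
  ramp <- function(n) {
    w <- rep(1, n)
    if (overlap_px > 0) {
      e <- pmin(seq_len(n), n + 1 - seq_len(n))
      w <- pmin(e / (overlap_px + 1), 1)
    }
    w
  }
  wt <- outer(ramp(d[1]), ramp(d[2]))
  offsets <- matrix(0L, length(tiles), 2)
  k <- 0L
  for (gi in seq_len(grid[1])) for (gj in seq_len(grid[2])) {
    k <- k + 1L
    tile <- tiles[[k]]
    pos <- c((gi - 1L) * step[1], (gj - 1L) * step[2])   # 0-based corner
    if (refine && overlap_px > 0 && k > 1L) {
      off <- refine_offset(acc, wacc, tile, pos, overlap_px)
      offsets[k, ] <- off
      pos <- pos + off
      pos <- pmin(pmax(pos, c(0L, 0L)), canvas_dim - d)
    }
    ri <- (pos[1] + 1):(pos[1] + d[1]); ci <- (pos[2] + 1):(pos[2] + d[2])
    acc[ri, ci] <- acc[ri, ci] + tile * wt
    wacc[ri, ci] <- wacc[ri, ci] + wt
  }
  img <- acc
  pos_w <- wacc > 0
  img[pos_w] <- acc[pos_w] / wacc[pos_w]
  structure(list(image = img, offsets = offsets), class = "mosaic")
}

# Best integer (row, col) offset of `tile` around nominal `pos` (0-based) by
# NCC against the already-populated canvas region.
refine_offset <- function(acc, wacc, tile, pos, overlap_px) {
  search <- overlap_px
  cd <- dim(acc); d <- dim(tile)
  canvas <- acc
  w <- wacc > 0
  canvas[w] <- acc[w] / wacc[w]
  score <- function(off) {
    p <- pos + off
    if (any(p < 0) || any(p + d > cd)) return(-Inf)
    ri <- (p[1] + 1):(p[1] + d[1]); ci <- (p[2] + 1):(p[2] + d[2])
    ov <- w[ri, ci]
    if (sum(ov) < 16) return(-Inf)
    u <- canvas[ri, ci][ov]; v <- tile[ov]
    u <- u - mean(u); v <- v - mean(v)
    den <- sqrt(sum(u^2) * sum(v^2))
    if (den > 0) sum(u * v) / den else 0   # featureless overlap: no preference
  }
  best <- score(c(0L, 0L)); best_off <- c(0L, 0L)   # nominal position wins ties
  for (dr in -search:search) for (dc in -search:search) {
    if (dr == 0 && dc == 0) next
    cc <- score(c(dr, dc))
    if (cc > best + 1e-12) { best <- cc; best_off <- c(dr, dc) }
  }
  as.integer(best_off)
}

#' Canvas size of a tile mosaic in millimetres
#'
#' @param tile_mm tile extent (mm, scalar or c(x, y)).
#' @param grid c(rows, cols).
#' @param overlap_mm seam overlap (mm).
#' @return Extent of the stitched canvas in mm per axis.
#' @export
mosaic_extent_mm <- function(tile_mm, grid, overlap_mm) {
  tile_mm * grid - overlap_mm * (grid - 1)
}
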