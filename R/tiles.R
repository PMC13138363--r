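#' Build an overlapping tile grid over an image
#'
#' Tiles of `tile_shape` are laid out with stride `tile - overlap` per axis;
#' the final tile per axis is clamped to the image edge so the union of tiles
#' covers every pixel. Images smaller than a tile get a single clamped tile
#' at (0, 0).
#'
#' @param image_shape c(width, height) px.
#' @param tile_shape c(width, height) px; default the 2024 x 1024 tiling used
#'   for whole-acquisition STEM segmentation.
#' @param overlap overlap in px, scalar or c(x, y); must be < tile dimension.
#' @return object of class `tile_grid`: list with `image_shape`, `tile_shape`
#'   (clamped to the image), `overlap`, and `offsets` (data.frame of 0-based
#'   top-left x, y).
#' @export
make_tile_grid <- function(image_shape, tile_shape = c(2024L, 1024L),
                           overlap = 256L) {
  image_shape <- as.integer(image_shape)
  tile_shape <- as.integer(tile_shape)
  if (length(overlap) == 1L) overlap <- c(overlap, overlap)
  overlap <- as.integer(overlap)
  if (any(overlap >= tile_shape))
    stopf("overlap (%s) must be smaller than the tile dimension (%s)",
          paste(overlap, collapse = "x"), paste(tile_shape, collapse = "x"))
  eff <- pmin(tile_shape, image_shape)
  overlap <- pmin(overlap, eff - 1L)
  axis_offsets <- function(img, tile, ov) {
    if (tile >= img) return(0L)
    stride <- tile - ov
    offs <- seq.int(0L, img - tile, by = stride)
    if (offs[length(offs)] + tile < img) offs <- c(offs, img - tile)
    offs
  }
  ox <- axis_offsets(image_shape[1], eff[1], overlap[1])
  oy <- axis_offsets(image_shape[2], eff[2], overlap[2])
  offsets <- expand.grid(x = ox, y = oy, KEEP.OUT.ATTRS = FALSE)
  g <- list(image_shape = image_shape, tile_shape = eff, overlap = overlap,
            offsets = offsets)
  class(g) <- "tile_grid"
  g
}

#' Extract one tile from an image
#' @param image matrix (width x height).
#' @param grid a `tile_grid`.
#' @param i tile index (row of `grid$offsets`).
#' @return matrix of the tile.
#' @export
crop_tile <- function(image, grid, i) {
  o <- grid$offsets[i, ]
  tw <- grid$tile_shape[1]; th <- grid$tile_shape[2]
  image[(o$x + 1L):(o$x + tw), (o$y + 1L):(o$y + th), drop = FALSE]
}

#' Reassemble tile masks into a whole-image mask
#'
#' Overlap is resolved by center-crop priority: each pixel is taken from the
#' tile whose center is nearest (ties broken toward the lower offset), so
#' every pixel is assigned exactly once and predictions near tile borders are
#' discarded in favor of better-contextualized interior predictions.
#'
#' @param tile_masks list of matrices, one per row of `grid$offsets`, each of
#'   `grid$tile_shape` size.
#' @param grid the `tile_grid` used to cut the tiles.
#' @param image_shape optional c(width, height); defaults to the grid's.
#' @return integer matrix of `image_shape`.
#' @export
reassemble <- function(tile_masks, grid, image_shape = grid$image_shape) {
  offs <- grid$offsets
  n <- nrow(offs)
  if (length(tile_masks) != n)
    stopf("expected %d tile masks, got %d", n, length(tile_masks))
  for (i in seq_len(n)) {
    if (is.null(tile_masks[[i]]))
      stopf("missing tile mask for offset (%d, %d)", offs$x[i], offs$y[i])
    if (!all(dim(tile_masks[[i]]) == grid$tile_shape))
      stopf("tile mask %d has wrong shape", i)
  }
  tw <- grid$tile_shape[1]; th <- grid$tile_shape[2]
  ox <- sort(unique(offs$x)); oy <- sort(unique(offs$y))
  owner_axis <- function(coords, o, tdim) {
    centers <- o + tdim / 2
    if (length(o) == 1L) return(rep(1L, length(coords)))
    mids <- (centers[-length(centers)] + centers[-1]) / 2
    findInterval(coords, mids, left.open = TRUE) + 1L
  }
  own_x <- owner_axis(0:(image_shape[1] - 1L), ox, tw)
  own_y <- owner_axis(0:(image_shape[2] - 1L), oy, th)
  out <- matrix(0L, image_shape[1], image_shape[2])
  for (i in seq_len(n)) {
    kx <- match(offs$x[i], ox); ky <- match(offs$y[i], oy)
    xs <- which(own_x == kx); ys <- which(own_y == ky)
    if (!length(xs) || !length(ys)) next
    out[xs, ys] <- tile_masks[[i]][xs - offs$x[i], ys - offs$y[i]]
  }
  out
}
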