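#' Distance-map regression target
#'
#' For each organ mask, the Euclidean distance transform inside the mask
#' (distance of every foreground pixel to its nearest background pixel) is
#' normalised by that organ's maximum, giving a shape prior in \[0, 1\] that
#' peaks at the organ's medial axis. The per-organ maps are then summed
#' pixel-wise into one regression channel; since the organ masks are disjoint
#' this is equivalently a mosaic of the three normalised transforms.
#'
#' An all-zero mask contributes an all-zero map (no division takes place).
#'
#' @param masks named list of binary matrices (any subset of organs).
#' @return numeric matrix, zero outside all organs, each organ's interior in
#'   (0, 1\] with maximum exactly 1 for non-empty organs.
#' @export
#' @examples
#' m <- matrix(0L, 9, 9); m[3:7, 3:7] <- 1L
#' dm <- distance_map(list(square = m))
#' dm[5, 5]  # 1: the centre of a 5x5 square is 3 pixels from background
distance_map <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1)
  shp <- dim(masks[[1]])
  out <- matrix(0, shp[1], shp[2])
  for (m in masks) {
    stopifnot(all(dim(m) == shp))
    if (sum(m) == 0) next
    d <- as.matrix(EBImage::distmap(matrix(as.numeric(m != 0), shp[1], shp[2])))
    out <- out + d / max(d)
  }
  out
}

# 3x3 (8-connected) binary erosion treating outside-the-image as background
erode8 <- function(mask) {
  m <- mask != 0
  H <- nrow(m); W <- ncol(m)
  p <- matrix(FALSE, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  out <- m
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    out <- out & p[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)]
  }
  out
}

#' Contour-map classification target
#'
#' The binary edge of an organ mask: foreground pixels removed by a 3x3
#' (8-connected) morphological erosion. Pixels on the image border count as
#' edge when foreground, since the outside of the image is treated as
#' background. The contour is non-empty exactly when the mask is; a
#' single-pixel mask is its own contour.
#'
#' @param mask binary matrix.
#' @return 0/1 integer matrix of the same shape.
#' @export
#' @examples
#' m <- matrix(0L, 5, 5); m[2:4, 2:4] <- 1L
#' sum(contour_map(m))  # 8: erosion of a 3x3 square leaves only its centre
contour_map <- function(mask) {
  (mask != 0 & !erode8(mask)) * 1L
}
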