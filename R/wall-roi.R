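#' Build the 2-pixel rectal-wall ring
#'
#' The wall is the filled rectum mask minus its double morphological erosion
#' with a 3x3 square structuring element: the discrete realisation of
#' expanding the rectum contour inwards by 2 pixels. If two erosions empty
#' the mask (a very small rectum) the whole mask is used as the wall and a
#' warning is emitted.
#'
#' @param rectumMask logical/0-1 matrix, the filled rectum.
#' @param sliceIndex slice index carried into the result.
#' @return a [WallROI].
#' @export
buildWallRing <- function(rectumMask, sliceIndex = 1L) {
  m <- rectumMask != 0
  if (!any(m)) stop("empty rectum mask")
  storage.mode(rectumMask) <- "double"
  brush <- EBImage::makeBrush(3, shape = "box")
  er2 <- EBImage::erode(EBImage::erode(rectumMask * 1, brush), brush)
  inner <- er2 > 0.5
  if (!any(inner)) {
    warning("rectum too small for a 2-pixel wall; using the whole mask")
    wall <- m
  } else {
    wall <- m & !inner
  }
  new("WallROI", wallMask = wall, sourceMask = m,
      sliceIndex = as.integer(sliceIndex))
}

#' Tile 8x8 subimages along the wall ring
#'
#' One window is generated per wall pixel at 1-pixel intervals: the window's
#' top-left anchor is placed 3 pixels up and left of the wall pixel, so the
#' generating pixel sits in the window's central 2x2 block and, where the
#' 2-pixel band runs locally straight, the paired windows of the two band
#' pixels each span 3 pixels beyond the band on either side (3 + 2 + 3 = 8).
#' Duplicate anchors are removed and anchors are ordered row-major, making
#' the window set deterministic. Windows that would cross the slice border
#' are dropped (not padded) and counted in `nClipped`.
#'
#' @param wall a [WallROI].
#' @param image a [SliceImage] sharing the wall's dimensions.
#' @param side window side length in pixels.
#' @return a [SubimageSet]; zero windows if the wall is empty.
#' @export
tileSubimages <- function(wall, image, side = 8L) {
  px <- image@pixels
  if (!identical(dim(wall@wallMask), dim(px)))
    stop("wall mask and image dimensions differ")
  nr <- nrow(px); nc <- ncol(px)
  idx <- which(wall@wallMask, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(new("SubimageSet", pixels = array(0, c(side, side, 0)),
               anchors = matrix(0L, 0, 2), sliceIndex = wall@sliceIndex,
               nClipped = 0L))
  }
  # anchors in 0-based coordinates: wall pixel at window position (3, 3)
  a <- cbind(idx[, 1] - 1L - 3L, idx[, 2] - 1L - 3L)
  a <- unique(a)
  ok <- a[, 1] >= 0 & a[, 2] >= 0 & a[, 1] + side <= nr & a[, 2] + side <= nc
  nClipped <- sum(!ok)
  if (nClipped > 0)
    message(nClipped, " window(s) clipped at the slice border on slice ",
            wall@sliceIndex)
  a <- a[ok, , drop = FALSE]
  a <- a[order(a[, 1], a[, 2]), , drop = FALSE]   # row-major
  n <- nrow(a)
  out <- array(0, c(side, side, n))
  for (i in seq_len(n))
    out[, , i] <- px[(a[i, 1] + 1):(a[i, 1] + side),
                     (a[i, 2] + 1):(a[i, 2] + side)]
  colnames(a) <- c("row", "col")
  new("SubimageSet", pixels = out, anchors = a,
      sliceIndex = wall@sliceIndex, nClipped = as.integer(nClipped))
}

#' Plot the wall ring and window anchors over a slice
#'
#' Debug overlay in the spirit of a contour QA view: slice intensities in
#' grey, rectum mask outline, wall ring, and window anchor positions.
#'
#' @param image a [SliceImage].
#' @param wall a [WallROI].
#' @param subimages optionally a [SubimageSet] whose anchors are marked.
#' @param ... passed to [graphics::image].
#' @return invisibly `NULL`; called for its plot side effect.
#' @export
plotWallOverlay <- function(image, wall, subimages = NULL, ...) {
  px <- image@pixels
  graphics::image(0:(ncol(px) - 1), 0:(nrow(px) - 1), t(px)[, nrow(px):1],
                  col = grDevices::gray.colors(64), xlab = "col",
                  ylab = "row", ...)
  w <- which(wall@wallMask, arr.ind = TRUE)
  graphics::points(w[, 2] - 1, nrow(px) - w[, 1], pch = 15, cex = 0.4,
                   col = "green3")
  if (!is.null(subimages) && nrow(subimages@anchors) > 0)
    graphics::points(subimages@anchors[, 2], nrow(px) - 1 -
                       subimages@anchors[, 1], pch = 3, cex = 0.3,
                     col = "orange")
  invisible(NULL)
}
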