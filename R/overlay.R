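# Qualitative overlay export: ground-truth boundary in red, predicted
# boundary in green, their overlap in yellow, over a grayscale background.

#' Write a boundary overlay image
#'
#' Renders one axial slice of the background volume in grayscale and draws
#' mask boundaries on top: ground truth red, prediction green, overlapping
#' boundary pixels yellow. Minimal plumbing for visual inspection.
#'
#' @param gt ground-truth `MASK` [ImageVolume-class] (or array).
#' @param pred predicted `MASK` [ImageVolume-class] (or array).
#' @param background volume to display (CT or PET), same grid.
#' @param path output PNG file.
#' @param slice axial (z) slice index for 3D inputs; defaults to the slice
#'   with the most ground-truth voxels (middle slice if the mask is empty).
#' @return `path`, invisibly.
#' @export
overlaySlice <- function(gt, pred, background, path, slice = NULL) {
  g <- .asMaskArray(gt)
  p <- .asMaskArray(pred)
  b <- if (is(background, "ImageVolume")) background@data
  else as.array(background)
  if (!identical(dim(g), dim(p)) || !identical(dim(g), dim(b)))
    stop("overlay inputs must share one grid")
  if (length(dim(g)) == 3L) {
    if (is.null(slice)) {
      per <- apply(g, 3L, sum)
      slice <- if (max(per) > 0) which.max(per) else ceiling(dim(g)[3] / 2)
    }
    if (slice < 1L || slice > dim(g)[3])
      stop("slice ", slice, " out of range 1..", dim(g)[3])
    g <- g[, , slice]
    p <- p[, , slice]
    b <- b[, , slice]
  }
  gb <- .boundaryMask(g)
  pb <- .boundaryMask(p)
  bg <- b - min(b)
  if (max(bg) > 0) bg <- bg / max(bg)
  img <- array(bg, c(dim(bg), 3L))
  red <- gb & !pb
  green <- pb & !gb
  both <- gb & pb
  ch <- function(i) {
    m <- img[, , i]
    m[red] <- c(1, 0, 0)[i]
    m[green] <- c(0, 1, 0)[i]
    m[both] <- c(1, 1, 0)[i]
    m
  }
  for (i in 1:3) img[, , i] <- ch(i)
  # image files index rows from the top; our arrays are (x, y)
  png::writePNG(aperm(img, c(2, 1, 3)), path)
  invisible(path)
}
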