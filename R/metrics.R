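# Segmentation evaluation: Dice similarity, 95th-percentile Hausdorff
# distance, precision/recall, and the fold-aggregation conventions
# (arithmetic fold average; median; maximum absolute deviation of any fold
# from that median).

.asMaskArray <- function(x) {
  if (is(x, "ImageVolume")) x <- x@data
  x <- as.array(x)
  if (!all(x %in% c(0, 1, FALSE, TRUE))) stop("mask must be binary")
  x * 1
}

#' Dice similarity coefficient
#'
#' `DSC(x, y) = 2 |x intersect y| / (|x| + |y|)` on voxel counts. When both
#' masks are empty the conventional value 1 is returned, carrying attribute
#' `flagged = TRUE`.
#'
#' @param x,y binary masks ([ImageVolume-class] or arrays) of equal shape.
#' @return DSC in `[0, 1]`.
#' @examples
#' a <- matrix(0, 8, 8); a[2:4, 2:4] <- 1
#' dice(a, a)
#' @export
dice <- function(x, y) {
  x <- .asMaskArray(x)
  y <- .asMaskArray(y)
  if (!identical(dim(x), dim(y))) stop("mask shapes differ")
  nx <- sum(x)
  ny <- sum(y)
  if (nx + ny == 0) return(structure(1, flagged = TRUE))
  2 * sum(x * y) / (nx + ny)
}

# boundary voxels: mask voxels with >= 1 face-adjacent background neighbour
# (positions outside the grid count as background)
.boundaryMask <- function(m) {
  d <- dim(m)
  r <- length(d)
  hasBg <- array(FALSE, d)
  for (ax in seq_len(r)) {
    n <- d[ax]
    lo <- vector("list", r); hi <- vector("list", r)
    for (i in seq_len(r)) lo[[i]] <- hi[[i]] <- seq_len(d[i])
    lo[[ax]] <- c(1L, seq_len(n - 1L))   # neighbour at -1 (edge self -> bg below)
    hi[[ax]] <- c(seq_len(n - 1L) + 1L, n)
    shLo <- do.call(`[`, c(list(m), lo, list(drop = FALSE)))
    shHi <- do.call(`[`, c(list(m), hi, list(drop = FALSE)))
    # grid-edge voxels border the outside, which is background
    edge <- array(FALSE, d)
    idx <- function(k) {
      a <- lapply(d, seq_len)
      a[[ax]] <- k
      do.call(`[<-`, c(list(edge), a, list(value = TRUE)))
    }
    edge <- idx(1L)
    edge <- idx(n)
    hasBg <- hasBg | (shLo == 0) | (shHi == 0) | edge
  }
  m == 1 & hasBg
}

# physical (mm) coordinates of boundary voxels
.boundaryCoords <- function(m, spacing) {
  b <- which(.boundaryMask(m), arr.ind = TRUE)
  if (length(b) == 0) return(matrix(numeric(0), 0, length(spacing)))
  sweep(b - 1, 2L, spacing, "*")
}

# directed nearest-neighbour distances from each row of A to the set B
.directedDists <- function(A, B) {
  # squared cross distances via the expansion ||a-b||^2 = |a|^2 + |b|^2 - 2ab
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(apply(d2, 1L, min), 0))
}

#' 95th-percentile Hausdorff distance
#'
#' Boundary voxels (mask voxels with a face-adjacent background neighbour)
#' are mapped to physical coordinates via `spacing`; directed nearest-
#' boundary Euclidean distances are computed both ways. The default pools
#' the two directed distance sets and takes their 95th percentile (linear
#' interpolation between order statistics); `mode = "max_directed"` instead
#' takes the maximum of the two directed 95th percentiles.
#'
#' @param x,y binary masks of equal shape, both non-empty.
#' @param spacing mm per voxel along each axis.
#' @param mode `"pooled"` (default) or `"max_directed"`.
#' @param percentile percentile of the boundary distances (default 95).
#' @return Distance in millimetres.
#' @export
hd95 <- function(x, y, spacing = rep(1, length(dim(.asMaskArray(x)))),
                 mode = c("pooled", "max_directed"), percentile = 95) {
  mode <- match.arg(mode)
  x <- .asMaskArray(x)
  y <- .asMaskArray(y)
  if (!identical(dim(x), dim(y))) stop("mask shapes differ")
  if (sum(x) == 0 || sum(y) == 0)
    stop("undefined distance: ",
         paste(c("first", "second")[c(sum(x) == 0, sum(y) == 0)],
               collapse = " and "), " mask is empty")
  A <- .boundaryCoords(x, spacing)
  B <- .boundaryCoords(y, spacing)
  dxy <- .directedDists(A, B)
  dyx <- .directedDists(B, A)
  p <- percentile / 100
  if (mode == "pooled") unname(quantile(c(dxy, dyx), p, type = 7))
  else max(quantile(dxy, p, type = 7), quantile(dyx, p, type = 7))
}

#' Voxel precision and recall
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` between a ground
#' truth and a predicted mask. A 0/0 ratio returns 0 with attribute
#' `flagged = TRUE`.
#'
#' @param truth,pred binary masks of equal shape (truth first).
#' @return Named numeric `c(precision, recall)`.
#' @export
precisionRecall <- function(truth, pred) {
  t <- .asMaskArray(truth)
  p <- .asMaskArray(pred)
  if (!identical(dim(t), dim(p))) stop("mask shapes differ")
  tp <- sum(t * p)
  fp <- sum((1 - t) * p)
  fn <- sum(t * (1 - p))
  prec <- if (tp + fp == 0) structure(0, flagged = TRUE) else tp / (tp + fp)
  rec <- if (tp + fn == 0) structure(0, flagged = TRUE) else tp / (tp + fn)
  c(precision = prec, recall = rec)
}

#' Per-case metric report row
#'
#' Computes DSC, HD95, precision and recall for one case. An undefined HD95
#' (either mask empty) is reported as `NA` rather than imputed.
#'
#' @param truth,pred binary masks of equal shape.
#' @param spacing mm per voxel.
#' @param id,center case identifiers recorded in the row.
#' @return One-row `data.frame` with columns `case, center, dsc, hd95,
#'   precision, recall`.
#' @export
caseMetrics <- function(truth, pred, spacing = rep(1, 3), id = "",
                        center = "") {
  h <- tryCatch(hd95(truth, pred, spacing), error = function(e) NA_real_)
  pr <- precisionRecall(truth, pred)
  data.frame(case = id, center = center, dsc = as.numeric(dice(truth, pred)),
             hd95 = as.numeric(h), precision = as.numeric(pr["precision"]),
             recall = as.numeric(pr["recall"]), stringsAsFactors = FALSE)
}

#' Aggregate per-fold means across folds
#'
#' Given per-fold mean metrics (one row per fold), computes for every numeric
#' column the arithmetic fold average, the median across folds, and the
#' maximum absolute deviation of any fold from that median — the reporting
#' convention for leave-one-center cross-validation (the deviation is not a
#' standard deviation). `NA` fold entries (e.g. undefined HD95) are dropped
#' per metric.
#'
#' @param foldMeans `data.frame` of per-fold mean metrics, or a numeric
#'   vector of one metric's fold values.
#' @return A [FoldSummary-class].
#' @examples
#' summarizeFolds(data.frame(dsc = c(0.84, 0.80, 0.81)))
#' @export
summarizeFolds <- function(foldMeans) {
  if (is.numeric(foldMeans)) foldMeans <- data.frame(value = foldMeans)
  num <- foldMeans[vapply(foldMeans, is.numeric, logical(1))]
  if (nrow(num) < 1L) stop("need at least one fold")
  agg <- function(f) vapply(num, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else f(v)
  }, numeric(1))
  med <- agg(median)
  dev <- vapply(seq_along(num), function(i) {
    v <- num[[i]][!is.na(num[[i]])]
    if (length(v) == 0) NA_real_ else max(abs(v - med[i]))
  }, numeric(1))
  names(dev) <- names(num)
  new("FoldSummary", folds = foldMeans, average = agg(mean),
      medianRow = med, maxDeviation = dev)
}
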