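# Modality normalization, augmentation, and dataset splitting.

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Clip and rescale a CT volume
#'
#' Clips Hounsfield values to `[-1024, 1024]` and maps that range linearly
#' onto `[-1, 1]` (division by 1024 after clipping). Shape and spacing are
#' unchanged.
#'
#' @param ct a CT [ImageVolume-class].
#' @return A CT [ImageVolume-class] with values in `[-1, 1]`.
#' @export
clipScaleCT <- function(ct) {
  stopifnot(is(ct, "ImageVolume"))
  if (ct@modality != "CT") stop("clipScaleCT expects a CT volume")
  if (any(!is.finite(ct@data))) stop("CT volume contains non-finite values")
  imageVolume(pmin(pmax(ct@data, -1024), 1024) / 1024,
              spacing = ct@spacing, modality = "CT", id = ct@id)
}

#' Z-score normalize a PET volume
#'
#' Standardizes the whole volume to mean 0 and (population) standard
#' deviation 1, `z = (x - mu) / sigma`, with statistics computed over all
#' voxels of the stored volume.
#'
#' @param pet a PET [ImageVolume-class].
#' @return A standardized PET [ImageVolume-class].
#' @export
zscorePET <- function(pet) {
  stopifnot(is(pet, "ImageVolume"))
  if (pet@modality != "PET") stop("zscorePET expects a PET volume")
  if (any(!is.finite(pet@data))) stop("PET volume contains non-finite values")
  mu <- mean(pet@data)
  sigma <- sqrt(mean((pet@data - mu)^2))
  if (sigma == 0)
    stop("degenerate input: constant PET volume has zero standard deviation")
  imageVolume((pet@data - mu) / sigma, spacing = pet@spacing,
              modality = "PET", id = pet@id)
}

# flip one in-plane axis (1 = x "horizontal", 2 = y "vertical") of an array
.flipAxis <- function(a, axis) {
  idx <- rev(seq_len(dim(a)[axis]))
  if (length(dim(a)) == 2L) {
    if (axis == 1L) a[idx, , drop = FALSE] else a[, idx, drop = FALSE]
  } else {
    if (axis == 1L) a[idx, , , drop = FALSE] else a[, idx, , drop = FALSE]
  }
}

# right-angle rotation by k * 90 degrees in the axial (x, y) plane
.rot90k <- function(a, k) {
  k <- k %% 4L
  if (k == 0L) return(a)
  d <- length(dim(a))
  if (k %in% c(1L, 3L) && dim(a)[1] != dim(a)[2])
    stop("90-degree rotation requires a square axial plane")
  tr <- function(m) if (d == 2L) t(m) else aperm(m, c(2, 1, 3))
  for (i in seq_len(k)) a <- .flipAxis(tr(a), 1L)
  a
}

# small-angle axial rotation about the plane center; interp "linear"|"nearest"
.rotateSmall <- function(a, thetaDeg, interp) {
  d <- dim(a)
  th <- thetaDeg * pi / 180
  cx <- (d[1] + 1) / 2
  cy <- (d[2] + 1) / 2
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  # inverse mapping: sample source coords rotated by -theta
  sx <- cx + cos(th) * (g$x - cx) + sin(th) * (g$y - cy)
  sy <- cy - sin(th) * (g$x - cx) + cos(th) * (g$y - cy)
  samplePlane <- function(m) {
    if (interp == "nearest") {
      ix <- pmin(pmax(round(sx), 1), d[1])
      iy <- pmin(pmax(round(sy), 1), d[2])
      v <- m[cbind(ix, iy)]
    } else {
      x0 <- pmin(pmax(floor(sx), 1), d[1]); x1 <- pmin(x0 + 1, d[1])
      y0 <- pmin(pmax(floor(sy), 1), d[2]); y1 <- pmin(y0 + 1, d[2])
      fx <- pmin(pmax(sx - x0, 0), 1); fy <- pmin(pmax(sy - y0, 0), 1)
      v <- m[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
        m[cbind(x1, y0)] * fx * (1 - fy) +
        m[cbind(x0, y1)] * (1 - fx) * fy +
        m[cbind(x1, y1)] * fx * fy
    }
    out <- (sx >= 1 & sx <= d[1] & sy >= 1 & sy <= d[2]) * v
    dim(out) <- d[1:2]
    out
  }
  if (length(d) == 2L) samplePlane(a)
  else {
    out <- a
    for (z in seq_len(d[3])) out[, , z] <- samplePlane(a[, , z])
    out
  }
}

.transformPair <- function(sample, fn) {
  tv <- function(vol) {
    if (is.null(vol)) return(NULL)
    out <- fn(vol@data)
    if (vol@modality == "MASK") out <- (out > 0.5) * 1
    imageVolume(out, spacing = vol@spacing, modality = vol@modality,
                id = vol@id)
  }
  new("SamplePair", pet = tv(sample@pet), ct = tv(sample@ct),
      mask = tv(sample@mask), center = sample@center,
      patient = sample@patient)
}

#' Deterministic flips and rotations of a sample pair
#'
#' Applies the same spatial transform to PET, CT and mask. `flipSample` flips
#' horizontally (`axis = 1`, the x axis) or vertically (`axis = 2`);
#' `rotateSample` rotates in the axial plane, by right angles
#' (`k` quarter-turns) or by a small angle in degrees (`angle`; nearest
#' -neighbour resampling for masks, bilinear for images).
#'
#' @param sample a [SamplePair-class].
#' @param axis in-plane axis to flip (1 or 2).
#' @param k integer quarter-turns (used when `angle` is `NULL`).
#' @param angle optional small rotation angle in degrees.
#' @return The transformed [SamplePair-class].
#' @export
flipSample <- function(sample, axis) {
  stopifnot(is(sample, "SamplePair"), axis %in% c(1L, 2L))
  .transformPair(sample, function(a) .flipAxis(a, as.integer(axis)))
}

#' @rdname flipSample
#' @export
rotateSample <- function(sample, k = 1L, angle = NULL) {
  stopifnot(is(sample, "SamplePair"))
  if (is.null(angle))
    return(.transformPair(sample, function(a) .rot90k(a, as.integer(k))))
  tv <- function(vol) {
    if (is.null(vol)) return(NULL)
    interp <- if (vol@modality == "MASK") "nearest" else "linear"
    out <- .rotateSmall(vol@data, angle, interp)
    if (vol@modality == "MASK") out <- (out > 0.5) * 1
    imageVolume(out, spacing = vol@spacing, modality = vol@modality,
                id = vol@id)
  }
  new("SamplePair", pet = tv(sample@pet), ct = tv(sample@ct),
      mask = tv(sample@mask), center = sample@center,
      patient = sample@patient)
}

#' Seeded random augmentation of a sample pair
#'
#' Draws a random spatial transform — horizontal flip, vertical flip (each
#' with probability 1/2 when enabled) and a rotation (a quarter-turn drawn
#' uniformly, or a uniform angle in `[-15, 15]` degrees in small-angle mode)
#' — and applies it identically to PET, CT and mask. The same seed always
#' reproduces the same output; masks remain binary.
#'
#' @param sample a [SamplePair-class].
#' @param seed integer seed for the transform draw.
#' @param ops enabled operations, subset of `c("hflip", "vflip", "rotate")`.
#' @param smallAngle use continuous +/-15 degree rotations instead of
#'   quarter-turns.
#' @return An augmented [SamplePair-class] of unchanged shape.
#' @export
augmentSample <- function(sample, seed,
                          ops = c("hflip", "vflip", "rotate"),
                          smallAngle = FALSE) {
  stopifnot(is(sample, "SamplePair"),
            all(ops %in% c("hflip", "vflip", "rotate")))
  .withSeed(seed, {
    out <- sample
    if ("hflip" %in% ops && runif(1) < 0.5) out <- flipSample(out, 1L)
    if ("vflip" %in% ops && runif(1) < 0.5) out <- flipSample(out, 2L)
    if ("rotate" %in% ops) {
      if (smallAngle) out <- rotateSample(out, angle = runif(1, -15, 15))
      else out <- rotateSample(out, k = sample.int(4L, 1L) - 1L)
    }
    out
  })
}

#' Build a cross-validation split plan
#'
#' `LEAVE_ONE_CENTER` makes one fold per acquisition center whose test set is
#' exactly that center's samples (the evaluation protocol for multi-center
#' data). `RANDOM_80_20` makes a single fold with a seeded shuffle and
#' `round(0.2 * n)` test samples.
#'
#' @param samples list of [SamplePair-class] objects with unique patient ids.
#' @param strategy `"LEAVE_ONE_CENTER"` or `"RANDOM_80_20"`.
#' @param seed integer seed (used by the random strategy's shuffle).
#' @return A [SplitPlan-class].
#' @export
makeSplit <- function(samples, strategy = c("LEAVE_ONE_CENTER",
                                            "RANDOM_80_20"), seed = 1L) {
  strategy <- match.arg(strategy)
  if (length(samples) < 2L) stop("need at least 2 samples to split")
  ids <- vapply(samples, function(s) s@patient, character(1))
  if (anyDuplicated(ids)) stop("sample patient ids must be unique")
  centers <- vapply(samples, function(s) s@center, character(1))
  if (strategy == "LEAVE_ONE_CENTER") {
    uc <- sort(unique(centers))
    if (length(uc) < 2L)
      stop("LEAVE_ONE_CENTER requires samples from at least 2 centers")
    folds <- lapply(uc, function(ctr)
      list(train = ids[centers != ctr], test = ids[centers == ctr]))
  } else {
    nTest <- max(1L, round(0.2 * length(ids)))
    perm <- .withSeed(seed, sample(ids))
    folds <- list(list(train = sort(perm[-seq_len(nTest)]),
                       test = sort(perm[seq_len(nTest)])))
  }
  new("SplitPlan", folds = folds, strategy = strategy, seed = as.integer(seed))
}

#' Serialize / read a split plan
#'
#' Plans are stored as tab-separated text with one row per sample per fold
#' (`id`, `center`, `fold`, `role`) and a `#` header carrying strategy and
#' seed.
#'
#' @param plan a [SplitPlan-class].
#' @param samples the sample list the plan was built from (for center tags).
#' @param path output/input file.
#' @return `writeSplitPlan`: `path` invisibly; `readSplitPlan`: a
#'   [SplitPlan-class].
#' @export
writeSplitPlan <- function(plan, samples, path) {
  ids <- vapply(samples, function(s) s@patient, character(1))
  centers <- vapply(samples, function(s) s@center, character(1))
  rows <- do.call(rbind, lapply(seq_along(plan@folds), function(i) {
    f <- plan@folds[[i]]
    data.frame(id = c(f$train, f$test),
               center = centers[match(c(f$train, f$test), ids)],
               fold = i,
               role = rep(c("train", "test"),
                          c(length(f$train), length(f$test))))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# strategy=%s seed=%d", plan@strategy, plan@seed), con)
  write.table(rows, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSplitPlan
#' @export
readSplitPlan <- function(path) {
  header <- readLines(path, n = 1L)
  strategy <- sub(".*strategy=(\\S+).*", "\\1", header)
  seed <- as.integer(sub(".*seed=(-?\\d+).*", "\\1", header))
  rows <- read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  folds <- lapply(sort(unique(rows$fold)), function(i) {
    fr <- rows[rows$fold == i, ]
    list(train = fr$id[fr$role == "train"], test = fr$id[fr$role == "test"])
  })
  new("SplitPlan", folds = folds, strategy = strategy, seed = seed)
}
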