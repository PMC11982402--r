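# Synthetic co-registered PET-CT phantom generation.
#
# The phantom emulates the modality relationship that motivates anatomy-
# guided fusion: tumors are crisp-edged ellipsoids in CT (high-resolution
# anatomy, but at modest density contrast over a textured soft-tissue body)
# and bright-but-blurred uptake blobs in PET; PET-hot confounders with no CT
# correlate put a floor on the precision of any PET-only segmenter; a dense
# bone-like structure provides non-tumor anatomy. Everything is seeded.

#' Construct a phantom specification
#'
#' Defaults describe a desk-scale 64 x 64 axial slice at 1 mm spacing with
#' one tumor, two PET-hot confounders, modest tumor CT contrast (+60 HU over
#' a textured ~0-80 HU body) and strong-but-blurred PET tumor uptake (8 x
#' body baseline, 1.5-voxel blur).
#'
#' @param shape grid shape, length 2 or 3.
#' @param spacing mm per voxel (defaults to 1 mm per axis).
#' @param nTumors number of tumors.
#' @param tumorRadiusRange tumor semi-axis range in voxels.
#' @param tumorCTContrast additive HU shift of tumor tissue.
#' @param petTumorIntensity mean tumor uptake (body baseline is 1).
#' @param petBlurSigma Gaussian blur sd (voxels) applied to PET only.
#' @param nConfounders PET-hot regions excluded from the mask.
#' @param noiseSdCT,noiseSdPET additive Gaussian noise sd.
#' @param seed integer seed.
#' @param center acquisition-center tag.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(shape = c(64L, 64L),
                        spacing = rep(1, length(shape)),
                        nTumors = 1L, tumorRadiusRange = c(3, 7),
                        tumorCTContrast = 60, petTumorIntensity = 8,
                        petBlurSigma = 1.5, nConfounders = 2L,
                        noiseSdCT = 20, noiseSdPET = 0.2, seed = 1L,
                        center = "A") {
  new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      nTumors = as.integer(nTumors),
      tumorRadiusRange = as.numeric(tumorRadiusRange),
      tumorCTContrast = as.numeric(tumorCTContrast),
      petTumorIntensity = as.numeric(petTumorIntensity),
      petBlurSigma = as.numeric(petBlurSigma),
      nConfounders = as.integer(nConfounders),
      noiseSdCT = as.numeric(noiseSdCT), noiseSdPET = as.numeric(noiseSdPET),
      seed = as.integer(seed), center = as.character(center))
}

# separable Gaussian blur with boundary renormalization; sigma in voxels
.gaussBlur <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  r <- ceiling(3 * sigma)
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  num <- a
  den <- array(1, d)
  shift1 <- function(m, o) {  # shift first axis by o, zero fill
    n <- dim(m)[1]
    out <- array(0, dim(m))
    if (o >= 0) {
      if (o < n) {
        src <- seq_len(n - o)
        .subsetFirst(out, src + o, .subsetFirst(m, src))
      } else out
    } else {
      if (-o < n) {
        src <- seq(1 - o, n)
        .subsetFirst(out, src + o, .subsetFirst(m, src))
      } else out
    }
  }
  for (ax in seq_along(d)) {
    perm <- c(ax, setdiff(seq_along(d), ax))
    num <- aperm(num, perm)
    den <- aperm(den, perm)
    nn <- num * 0
    dd <- den * 0
    for (i in seq_along(w)) {
      o <- i - r - 1L
      nn <- nn + w[i] * shift1(num, o)
      dd <- dd + w[i] * shift1(den, o)
    }
    num <- aperm(nn, order(perm))
    den <- aperm(dd, order(perm))
  }
  num / den
}

# out[idxOrAll, ...] <- value / out[idx, ...] for arrays of rank 2 or 3
.subsetFirst <- function(m, idx, value) {
  r <- length(dim(m))
  if (missing(value)) {
    if (r == 2L) m[idx, , drop = FALSE] else m[idx, , , drop = FALSE]
  } else {
    if (r == 2L) m[idx, ] <- value else m[idx, , ] <- value
    m
  }
}

# binary ellipsoid rasterization on voxel centers (1-based grid)
.ellipsoidMask <- function(shape, center, semi) {
  r <- length(shape)
  axes <- lapply(seq_len(r), function(i)
    ((seq_len(shape[i]) - center[i]) / semi[i])^2)
  if (r == 2L) q <- outer(axes[[1]], axes[[2]], "+")
  else q <- outer(outer(axes[[1]], axes[[2]], "+"), axes[[3]], "+")
  (q <= 1) * 1
}

#' Generate one synthetic PET-CT sample
#'
#' Builds a co-registered PET/CT pair with ground-truth mask from a
#' [PhantomSpec-class]: air background (-1000 HU), an elliptical soft-tissue
#' body with smooth density texture, a dense bone-like structure (~700 HU),
#' crisp tumor ellipsoids at `tumorCTContrast` in CT, blurred tumor uptake
#' and PET-only confounders in PET, plus per-modality noise. The mask is
#' exactly the union of the unblurred tumor ellipsoids. Identical specs give
#' bit-identical samples.
#'
#' @param spec a [PhantomSpec-class].
#' @param id patient/sample identifier.
#' @return A [SamplePair-class] tagged with `spec@center`.
#' @export
generatePhantom <- function(spec, id = sprintf("phantom%04d", spec@seed)) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  .withSeed(spec@seed, .generatePhantomImpl(spec, id))
}

.generatePhantomImpl <- function(spec, id) {
  shp <- spec@shape
  r <- length(shp)
  bodyCenter <- (shp + 1) / 2
  bodySemi <- 0.42 * shp
  body <- .ellipsoidMask(shp, bodyCenter, bodySemi)

  # CT: air, textured soft tissue, dense structure
  ct <- array(-1000, shp)
  texture <- .gaussBlur(array(rnorm(prod(shp)), shp), 4)
  texture <- texture / max(sd(texture), 1e-12) * 25
  ct[body == 1] <- 40 + texture[body == 1]
  denseCenter <- bodyCenter + c(0, 0.22 * shp[2], rep(0, r - 2))
  denseSemi <- pmax(2, c(0.10, 0.07, 0.10)[seq_len(r)] * shp)
  dense <- .ellipsoidMask(shp, denseCenter, denseSemi) * body
  ct[dense == 1] <- 700

  # PET: low body uptake baseline
  pet <- array(0, shp)
  pet[body == 1] <- 1

  occupied <- dense  # placement must avoid existing structures
  mask <- array(0, shp)
  placeBlob <- function(occupied) {
    for (attempt in seq_len(1000L)) {
      semi <- runif(r, spec@tumorRadiusRange[1], spec@tumorRadiusRange[2])
      ctr <- bodyCenter + (runif(r, -1, 1) * (bodySemi - semi - 1.5))
      blob <- .ellipsoidMask(shp, ctr, semi)
      if (sum(blob) == 0) next
      if (all(body[blob == 1] == 1) && !any(occupied[blob == 1] == 1))
        return(blob)
    }
    stop("generation error: could not place a blob inside the body after ",
         "1000 attempts; shrink the tumors or enlarge the grid")
  }
  for (i in seq_len(spec@nTumors)) {
    blob <- placeBlob(occupied)
    mask <- pmax(mask, blob)
    occupied <- pmax(occupied, blob)
    ct[blob == 1] <- ct[blob == 1] + spec@tumorCTContrast
    pet[blob == 1] <- spec@petTumorIntensity
  }
  for (i in seq_len(spec@nConfounders)) {
    blob <- placeBlob(occupied)
    occupied <- pmax(occupied, blob)
    pet[blob == 1] <- spec@petTumorIntensity  # PET-hot, no CT correlate
  }

  pet <- .gaussBlur(pet, spec@petBlurSigma)
  if (spec@noiseSdCT > 0) ct <- ct + rnorm(prod(shp), sd = spec@noiseSdCT)
  if (spec@noiseSdPET > 0)
    pet <- pmax(pet + rnorm(prod(shp), sd = spec@noiseSdPET), 0)

  validatePair(
    imageVolume(pet, spec@spacing, "PET", paste0(id, "_pet")),
    imageVolume(ct, spec@spacing, "CT", paste0(id, "_ct")),
    imageVolume(mask, spec@spacing, "MASK", paste0(id, "_mask")),
    center = spec@center, patient = id)
}

#' Generate a seeded multi-center phantom dataset
#'
#' Draws deterministic per-sample seeds from `seed` and applies mild
#' per-center parameter jitter (noise levels and PET intensity scale) to
#' mimic the acquisition variation across centers that motivates learnable
#' normalization. The same call always reproduces the identical dataset.
#'
#' @param baseSpec a [PhantomSpec-class] used as template.
#' @param nPerCenter samples per center (>= 1).
#' @param centers character vector of center tags (>= 1).
#' @param seed integer master seed.
#' @return List of [SamplePair-class] objects, `nPerCenter * length(centers)`
#'   long, with unique patient ids.
#' @export
generateDataset <- function(baseSpec = phantomSpec(), nPerCenter = 4L,
                            centers = c("A", "B", "C"), seed = 1L) {
  stopifnot(nPerCenter >= 1L, length(centers) >= 1L)
  nTot <- nPerCenter * length(centers)
  seeds <- .withSeed(seed, sample.int(.Machine$integer.max - 1L, nTot))
  # per-center acquisition jitter (cycled for many centers)
  ctNoiseF <- rep(c(0.6, 1.0, 1.5, 0.8, 1.2), length.out = length(centers))
  petNoiseF <- rep(c(1.0, 1.4, 0.7, 1.2, 0.9), length.out = length(centers))
  petIntF <- rep(c(1.0, 0.85, 1.15, 0.95, 1.1), length.out = length(centers))
  out <- vector("list", nTot)
  k <- 0L
  for (ci in seq_along(centers)) {
    for (si in seq_len(nPerCenter)) {
      k <- k + 1L
      sp <- baseSpec
      sp@center <- centers[ci]
      sp@seed <- seeds[k]
      sp@noiseSdCT <- baseSpec@noiseSdCT * ctNoiseF[ci]
      sp@noiseSdPET <- baseSpec@noiseSdPET * petNoiseF[ci]
      sp@petTumorIntensity <- baseSpec@petTumorIntensity * petIntF[ci]
      out[[k]] <- generatePhantom(sp, id = sprintf("%s%03d", centers[ci], si))
    }
  }
  out
}

#' Write / read a phantom dataset as a NIfTI tree
#'
#' Writes `<id>_pet.nii.gz`, `<id>_ct.nii.gz`, `<id>_mask.nii.gz` per sample
#' plus a tab-separated `manifest.tsv` (id, center). `readPhantomDataset`
#' restores the sample list from such a tree.
#'
#' @param samples list of [SamplePair-class] objects.
#' @param dir dataset directory (created if missing).
#' @return `writePhantomDataset`: the manifest path, invisibly;
#'   `readPhantomDataset`: a list of [SamplePair-class] objects.
#' @export
writePhantomDataset <- function(samples, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(samples, function(s) {
    writeVolume(s@pet, file.path(dir, paste0(s@patient, "_pet.nii.gz")))
    writeVolume(s@ct, file.path(dir, paste0(s@patient, "_ct.nii.gz")))
    if (!is.null(s@mask))
      writeVolume(s@mask, file.path(dir, paste0(s@patient, "_mask.nii.gz")))
    data.frame(id = s@patient, center = s@center, stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.tsv")
  write.table(do.call(rbind, rows), manifest, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(manifest)
}

#' @rdname writePhantomDataset
#' @export
readPhantomDataset <- function(dir) {
  manifest <- read.delim(file.path(dir, "manifest.tsv"),
                         stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$id[i]
    maskPath <- file.path(dir, paste0(id, "_mask.nii.gz"))
    validatePair(
      readVolume(file.path(dir, paste0(id, "_pet.nii.gz")), "PET"),
      readVolume(file.path(dir, paste0(id, "_ct.nii.gz")), "CT"),
      if (file.exists(maskPath)) readVolume(maskPath, "MASK") else NULL,
      center = manifest$center[i], patient = id)
  })
}
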