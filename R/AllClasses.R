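#' @import methods
#' @importFrom stats median quantile rnorm runif sd
#' @importFrom utils head read.csv write.csv
#' @useDynLib anatofuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Scalar image volume with voxel spacing and modality
#'
#' A 2D or 3D scalar grid together with its physical voxel spacing in
#' millimetres and a modality tag. Arrays are indexed `(x, y)` for rank 2 and
#' `(x, y, z)` for rank 3 (column-major R convention); `spacing` follows the
#' same axis order. `MASK` volumes are constrained to values 0/1.
#'
#' @slot data numeric array of rank 2 or 3.
#' @slot spacing numeric, mm per voxel along each axis of `data`.
#' @slot modality one of `"PET"`, `"CT"`, `"MASK"`.
#' @slot id opaque identifier string.
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", modality = "character",
                 id = "character"))

setValidity("ImageVolume", function(object) {
  d <- dim(object@data)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    return("data must be an array of rank 2 or 3")
  if (length(object@spacing) != length(d))
    return(sprintf("spacing has %d entries but data has rank %d",
                   length(object@spacing), length(d)))
  if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    return("all spacing entries must be finite and > 0")
  if (!object@modality %in% c("PET", "CT", "MASK"))
    return("modality must be PET, CT or MASK")
  if (object@modality == "MASK") {
    if (any(!is.finite(object@data)))
      return("MASK volume contains non-finite values")
    if (!all(object@data %in% c(0, 1)))
      return("MASK volume must contain only 0/1 values")
  }
  TRUE
})

#' Construct an ImageVolume
#'
#' @param data numeric array (rank 2 or 3), or a matrix.
#' @param spacing voxel spacing in mm, one entry per axis (default 1 mm).
#' @param modality `"PET"`, `"CT"` or `"MASK"`.
#' @param id identifier string.
#' @return An [ImageVolume-class] object.
#' @export
imageVolume <- function(data, spacing = rep(1, length(dim(data))),
                        modality = c("PET", "CT", "MASK"), id = "") {
  modality <- match.arg(modality)
  data <- as.array(data)
  storage.mode(data) <- "double"
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      modality = modality, id = as.character(id))
}

setClassUnion("ImageVolumeOrNULL", c("ImageVolume", "NULL"))

#' Co-registered PET/CT sample with optional ground-truth mask
#'
#' Groups the two model inputs (PET uptake and CT attenuation on a common
#' voxel grid) with an optional binary tumor mask and acquisition metadata
#' used for leave-one-center splitting.
#'
#' @slot pet,ct [ImageVolume-class] objects on identical grids.
#' @slot mask optional `MASK` [ImageVolume-class] (may be `NULL` at inference).
#' @slot center acquisition-center tag.
#' @slot patient patient/sample identifier.
#' @seealso [validatePair()]
#' @export
setClass("SamplePair",
  representation(pet = "ImageVolume", ct = "ImageVolume",
                 mask = "ImageVolumeOrNULL", center = "character",
                 patient = "character"))

setValidity("SamplePair", function(object) {
  if (object@pet@modality != "PET") return("pet slot must have modality PET")
  if (object@ct@modality != "CT") return("ct slot must have modality CT")
  msg <- .gridMismatch(object@pet, object@ct)
  if (!is.null(msg)) return(msg)
  if (!is.null(object@mask)) {
    if (object@mask@modality != "MASK") return("mask slot must be MASK")
    msg <- .gridMismatch(object@pet, object@mask)
    if (!is.null(msg)) return(msg)
  }
  TRUE
})

#' Synthetic PET-CT phantom specification
#'
#' Parameters controlling one synthetic co-registered PET-CT sample: grid
#' geometry, tumor geometry and contrast, the PET partial-volume blur, PET-hot
#' confounders without a CT correlate, per-modality noise, and the seed.
#' Defaults are desk-scale: a 64 x 64 axial slice at 1 mm spacing.
#'
#' @slot shape integer grid shape, length 2 or 3, `(x, y[, z])`.
#' @slot spacing mm per voxel.
#' @slot nTumors number of tumors (>= 0).
#' @slot tumorRadiusRange min/max tumor semi-axis, voxels.
#' @slot tumorCTContrast additive HU shift of tumor tissue over soft tissue.
#' @slot petTumorIntensity mean tracer uptake of tumor tissue (body baseline 1).
#' @slot petBlurSigma Gaussian blur sd (voxels) applied to the PET image only.
#' @slot nConfounders PET-hot regions with no CT correlate, excluded from mask.
#' @slot noiseSdCT,noiseSdPET additive Gaussian noise sd (HU / uptake units).
#' @slot seed integer seed; identical specs reproduce bit-identical samples.
#' @slot center acquisition-center tag carried to the sample.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric", nTumors = "integer",
                 tumorRadiusRange = "numeric", tumorCTContrast = "numeric",
                 petTumorIntensity = "numeric", petBlurSigma = "numeric",
                 nConfounders = "integer", noiseSdCT = "numeric",
                 noiseSdPET = "numeric", seed = "integer",
                 center = "character"))

setValidity("PhantomSpec", function(object) {
  if (!(length(object@shape) %in% c(2L, 3L)) || any(object@shape < 8L))
    return("shape must have 2 or 3 axes, each >= 8 voxels")
  if (length(object@spacing) != length(object@shape))
    return("spacing must match shape rank")
  if (object@tumorRadiusRange[1] > object@tumorRadiusRange[2])
    return("tumorRadiusRange must be (min, max) with min <= max")
  if (object@petBlurSigma < 0 || object@noiseSdCT < 0 || object@noiseSdPET < 0)
    return("blur sigma and noise sds must be >= 0")
  if (object@nTumors < 0L || object@nConfounders < 0L)
    return("counts must be >= 0")
  TRUE
})

#' Segmentation model configuration
#'
#' Describes the fusion segmentation network: dimensionality, the encoder
#' filter schedule, the zero-layer stem, squeeze-and-excite reduction, and the
#' fusion/guidance wiring. The default filter schedule decreases with depth,
#' `c(128, 64, 32, 16)`; set `reverseFilters = TRUE` for the conventional
#' increasing ordering.
#'
#' @slot dims 2 or 3 (spatial dimensionality).
#' @slot encoderFilters integer filter count per encoder stage.
#' @slot zeroLayerFilters filters F of the zero-layer stem convolution.
#' @slot zeroLayerKernel kernel size k of the stem convolution (odd).
#' @slot seReduction squeeze-and-excite bottleneck reduction ratio r;
#'   bottleneck width is `max(1, C / r)`.
#' @slot fusionActivation `"relu"` (default) or `"sigmoid"` applied after the
#'   additive fusion.
#' @slot fusionConv whether the post-fusion 1x1 convolution is present.
#' @slot normEpsInit initial value of the learnable normalization stabilizer.
#' @slot reverseFilters apply the filter schedule in reversed order.
#' @slot useZeroLayer include the learnable-normalization zero layers (when
#'   `FALSE` the stem is a plain convolution + ReLU).
#' @slot useSE include squeeze-and-excite channel attention in the encoders.
#' @slot guidance `"ct"` (anatomy guidance, default) or `"pet"`.
#' @export
setClass("ModelConfig",
  representation(dims = "integer", encoderFilters = "integer",
                 zeroLayerFilters = "integer", zeroLayerKernel = "integer",
                 seReduction = "integer", fusionActivation = "character",
                 fusionConv = "logical", normEpsInit = "numeric",
                 reverseFilters = "logical", useZeroLayer = "logical",
                 useSE = "logical", guidance = "character"))

setValidity("ModelConfig", function(object) {
  if (!object@dims %in% c(2L, 3L)) return("dims must be 2 or 3")
  if (any(object@encoderFilters < 1L)) return("all filter counts must be >= 1")
  if (object@zeroLayerFilters < 1L) return("zeroLayerFilters must be >= 1")
  if (object@zeroLayerKernel %% 2L != 1L) return("zeroLayerKernel must be odd")
  if (object@seReduction < 1L) return("seReduction must be >= 1")
  if (!object@fusionActivation %in% c("relu", "sigmoid"))
    return("fusionActivation must be relu or sigmoid")
  if (object@normEpsInit <= 0) return("normEpsInit must be > 0")
  if (!object@guidance %in% c("ct", "pet"))
    return("guidance must be ct or pet")
  TRUE
})

#' Training configuration
#'
#' Optimization schedule: Adam at initial learning rate 0.005, batch size 1,
#' learning rate multiplied by `plateauFactor` whenever the monitored loss
#' fails to improve for `plateauPatience` consecutive epochs.
#'
#' @slot lr initial learning rate.
#' @slot plateauPatience epochs without improvement before lr reduction.
#' @slot plateauFactor multiplicative lr reduction factor in (0, 1).
#' @slot minLr learning-rate floor.
#' @slot maxEpochs number of training epochs.
#' @slot loss `"dice"` (soft Dice) or `"bce_dice"`.
#' @slot seed seed governing weight init, shuffling and augmentation.
#' @slot threshold probability threshold for binarizing predictions.
#' @slot valFraction fraction of training samples held out for monitoring
#'   when no validation set is supplied.
#' @slot augment augmentation ops applied online during training (subset of
#'   `"hflip"`, `"vflip"`, `"rotate"`; empty vector disables augmentation).
#' @export
setClass("TrainConfig",
  representation(lr = "numeric", plateauPatience = "integer",
                 plateauFactor = "numeric", minLr = "numeric",
                 maxEpochs = "integer", loss = "character", seed = "integer",
                 threshold = "numeric", valFraction = "numeric",
                 augment = "character"))

setValidity("TrainConfig", function(object) {
  if (object@lr <= 0) return("lr must be > 0")
  if (object@plateauPatience < 1L) return("plateauPatience must be >= 1")
  if (object@plateauFactor <= 0 || object@plateauFactor >= 1)
    return("plateauFactor must be in (0, 1)")
  if (!object@loss %in% c("dice", "bce_dice"))
    return("loss must be dice or bce_dice")
  if (!all(object@augment %in% c("hflip", "vflip", "rotate")))
    return("augment entries must be hflip, vflip or rotate")
  TRUE
})

#' Dataset split plan
#'
#' Folds of train/test sample ids under one of the two evaluation protocols:
#' leave-one-center-out (each fold tests on all samples of one center) or a
#' seeded random 80/20 split.
#'
#' @slot folds list; each element has `$train` and `$test` character id sets.
#' @slot strategy `"LEAVE_ONE_CENTER"` or `"RANDOM_80_20"`.
#' @slot seed integer seed used for shuffling.
#' @export
setClass("SplitPlan",
  representation(folds = "list", strategy = "character", seed = "integer"))

setValidity("SplitPlan", function(object) {
  if (!object@strategy %in% c("LEAVE_ONE_CENTER", "RANDOM_80_20"))
    return("unknown strategy")
  for (f in object@folds) {
    if (length(intersect(f$train, f$test)) > 0)
      return("train and test ids overlap within a fold")
  }
  TRUE
})

#' Cross-validation fold summary
#'
#' Per-fold mean metrics plus the aggregation conventions used for reporting:
#' arithmetic fold average, median across folds, and the maximum absolute
#' deviation of any fold from that median (not a standard deviation).
#'
#' @slot folds data.frame of per-fold mean metrics (one row per fold).
#' @slot average,medianRow,maxDeviation named numeric vectors per metric.
#' @export
setClass("FoldSummary",
  representation(folds = "data.frame", average = "numeric",
                 medianRow = "numeric", maxDeviation = "numeric"))

#' Fitted segmentation model
#'
#' Holds the architecture tag (`"fusion"` for the anatomy-guided model,
#' `"unet"` for the baseline encoder-decoder), the configuration, and the
#' parameter tensors.
#'
#' @slot arch `"fusion"` or `"unet"`.
#' @slot config [ModelConfig-class].
#' @slot params environment of named parameter tensors.
#' @slot inChannels input channel count (baseline UNet: 1 or 2).
#' @slot meta list of bookkeeping fields (init seed, baseline filters, ...).
#' @export
setClass("SegmentationModel",
  representation(arch = "character", config = "ModelConfig",
                 params = "environment", inChannels = "integer",
                 meta = "list"))

# shared grid check used by SamplePair validity and validatePair()
.gridMismatch <- function(a, b, tol = 1e-4) {
  da <- dim(a@data)
  db <- dim(b@data)
  if (!identical(da, db))
    return(sprintf("grid shape mismatch: %s is %s but %s is %s",
                   a@modality, paste(da, collapse = "x"),
                   b@modality, paste(db, collapse = "x")))
  rel <- abs(a@spacing - b@spacing) / pmax(a@spacing, b@spacing)
  if (any(rel > tol))
    return(sprintf("voxel spacing mismatch: (%s) vs (%s)",
                   paste(signif(a@spacing, 8), collapse = ", "),
                   paste(signif(b@spacing, 8), collapse = ", ")))
  NULL
}
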