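# Accessor generics and show methods.

#' @describeIn ImageVolume-class voxel data array
#' @param object an object of the documented class.
#' @export
setGeneric("volData", function(object) standardGeneric("volData"))
setMethod("volData", "ImageVolume", function(object) object@data)

#' @describeIn ImageVolume-class voxel spacing (mm per axis)
#' @export
setGeneric("volSpacing", function(object) standardGeneric("volSpacing"))
setMethod("volSpacing", "ImageVolume", function(object) object@spacing)

#' @describeIn ImageVolume-class modality tag
#' @export
setGeneric("volModality", function(object) standardGeneric("volModality"))
setMethod("volModality", "ImageVolume", function(object) object@modality)

#' @describeIn ImageVolume-class identifier
#' @export
setGeneric("volId", function(object) standardGeneric("volId"))
setMethod("volId", "ImageVolume", function(object) object@id)

#' @describeIn SamplePair-class PET volume
#' @param object an object of the documented class.
#' @export
setGeneric("petVolume", function(object) standardGeneric("petVolume"))
setMethod("petVolume", "SamplePair", function(object) object@pet)

#' @describeIn SamplePair-class CT volume
#' @export
setGeneric("ctVolume", function(object) standardGeneric("ctVolume"))
setMethod("ctVolume", "SamplePair", function(object) object@ct)

#' @describeIn SamplePair-class ground-truth mask (or NULL)
#' @export
setGeneric("maskVolume", function(object) standardGeneric("maskVolume"))
setMethod("maskVolume", "SamplePair", function(object) object@mask)

#' @describeIn SamplePair-class acquisition center tag
#' @export
setGeneric("sampleCenter", function(object) standardGeneric("sampleCenter"))
setMethod("sampleCenter", "SamplePair", function(object) object@center)

#' @describeIn SamplePair-class patient/sample identifier
#' @export
setGeneric("samplePatient", function(object) standardGeneric("samplePatient"))
setMethod("samplePatient", "SamplePair", function(object) object@patient)

#' @describeIn SplitPlan-class list of folds (each with $train / $test ids)
#' @param object an object of the documented class.
#' @export
setGeneric("splitFolds", function(object) standardGeneric("splitFolds"))
setMethod("splitFolds", "SplitPlan", function(object) object@folds)

#' @describeIn FoldSummary-class per-fold mean metrics
#' @param object an object of the documented class.
#' @export
setGeneric("foldMetrics", function(object) standardGeneric("foldMetrics"))
setMethod("foldMetrics", "FoldSummary", function(object) object@folds)

#' @describeIn FoldSummary-class arithmetic fold average per metric
#' @export
setGeneric("foldAverage", function(object) standardGeneric("foldAverage"))
setMethod("foldAverage", "FoldSummary", function(object) object@average)

#' @describeIn FoldSummary-class median across folds per metric
#' @export
setGeneric("foldMedian", function(object) standardGeneric("foldMedian"))
setMethod("foldMedian", "FoldSummary", function(object) object@medianRow)

#' @describeIn FoldSummary-class maximum absolute fold deviation from median
#' @export
setGeneric("foldMaxDeviation",
           function(object) standardGeneric("foldMaxDeviation"))
setMethod("foldMaxDeviation", "FoldSummary",
          function(object) object@maxDeviation)

#' @describeIn SegmentationModel-class model configuration
#' @param object an object of the documented class.
#' @export
setGeneric("modelConfigOf", function(object) standardGeneric("modelConfigOf"))
setMethod("modelConfigOf", "SegmentationModel", function(object) object@config)

setMethod("show", "ImageVolume", function(object) {
  cat(sprintf("ImageVolume [%s] %s, spacing (%s) mm, range [%.4g, %.4g]\n",
              object@modality, paste(dim(object@data), collapse = "x"),
              paste(signif(object@spacing, 4), collapse = ", "),
              min(object@data), max(object@data)))
})

setMethod("show", "SamplePair", function(object) {
  cat(sprintf("SamplePair %s (center %s): grid %s%s\n",
              object@patient, object@center,
              paste(dim(object@pet@data), collapse = "x"),
              if (is.null(object@mask)) ", no mask"
              else sprintf(", mask voxels %d", sum(object@mask@data))))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan [%s] seed %d: %d fold(s)\n", object@strategy,
              object@seed, length(object@folds)))
  for (i in seq_along(object@folds))
    cat(sprintf("  fold %d: %d train / %d test\n", i,
                length(object@folds[[i]]$train),
                length(object@folds[[i]]$test)))
})

setMethod("show", "FoldSummary", function(object) {
  cat(sprintf("FoldSummary over %d fold(s)\n", nrow(object@folds)))
  m <- rbind(average = object@average, median = object@medianRow,
             `max deviation` = object@maxDeviation)
  print(round(m, 4))
})

setMethod("show", "SegmentationModel", function(object) {
  cat(sprintf("SegmentationModel [%s] %dD, %d stages, %d parameters\n",
              object@arch, object@config@dims,
              length(object@config@encoderFilters),
              countParameters(object)$total))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig %dD: filters [%s], zero layer F=%d k=%d (%s), SE r=%d (%s), %s-guided fusion (%s)\n",
    object@dims, paste(object@encoderFilters, collapse = ", "),
    object@zeroLayerFilters, object@zeroLayerKernel,
    if (object@useZeroLayer) "on" else "off", object@seReduction,
    if (object@useSE) "on" else "off", object@guidance,
    object@fusionActivation))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec %s @ (%s) mm: %d tumor(s) r=[%g, %g] vox, %d confounder(s), PET blur %g vox, seed %d, center %s\n",
    paste(object@shape, collapse = "x"),
    paste(object@spacing, collapse = ", "), object@nTumors,
    object@tumorRadiusRange[1], object@tumorRadiusRange[2],
    object@nConfounders, object@petBlurSigma, object@seed, object@center))
})
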