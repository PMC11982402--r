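# NIfTI (and single-slice PNG) volume input/output.
#
# The method assumes pre-registered PET/CT grids (as challenge datasets
# supply); affine handling is therefore reduced to spacing extraction and
# inputs on different grids are rejected rather than resampled.

#' Read a volume or mask from disk
#'
#' Reads a NIfTI (`.nii` / `.nii.gz`) volume — or an 8/16-bit grayscale PNG
#' for 2D slices — into an [ImageVolume-class]. Voxel spacing is taken from
#' the NIfTI header (`pixdim`); PNG values are rescaled to their integer
#' range and assigned unit spacing. `MASK` inputs are binarized by
#' thresholding at 0.5, tolerating lossily-compressed label files.
#'
#' @param path file to read.
#' @param modality `"PET"`, `"CT"` or `"MASK"`.
#' @param id identifier recorded on the volume; defaults to the file name.
#' @return An [ImageVolume-class].
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(imageVolume(array(7, c(4, 4, 4)), modality = "CT"), f)
#' readVolume(f, "CT")
#' @export
readVolume <- function(path, modality = c("PET", "CT", "MASK"),
                       id = basename(path)) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    px <- png::readPNG(path, info = TRUE)
    info <- attr(px, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    if (length(dim(px)) == 3L) px <- px[, , 1L]  # first channel of gray+alpha
    data <- t(px) * (2^depth - 1)  # back to integer scale; (x, y) indexing
    spacing <- c(1, 1)
  } else {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("cannot read NIfTI '", path,
                                             "': ", conditionMessage(e)))
    data <- array(as.numeric(img), dim(img))
    spacing <- RNifti::pixdim(img)[seq_along(dim(data))]
  }
  if (modality == "MASK") {
    if (any(!is.finite(data)))
      stop("mask '", path, "' contains non-finite values")
    data <- (data > 0.5) * 1
  }
  imageVolume(data, spacing = spacing, modality = modality, id = id)
}

#' Write a volume to disk
#'
#' Writes NIfTI with a 32-bit float payload (read/write round-trips are then
#' bit-exact) and the volume's spacing in the header. A `.png` path writes an
#' 8-bit grayscale slice of a 2D volume with values clipped to `[0, 255]`.
#'
#' @param vol an [ImageVolume-class].
#' @param path destination; extension selects the format.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "ImageVolume"))
  if (!dir.exists(dirname(path)))
    stop("cannot write volume: no such directory: ", dirname(path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (length(dim(vol@data)) != 2L) stop("PNG output is for 2D slices only")
    png::writePNG(t(pmin(pmax(vol@data, 0), 255)) / 255, path)
    return(invisible(path))
  }
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Validate co-registration and assemble a sample pair
#'
#' Checks that PET, CT and (optionally) the mask live on identical grids:
#' element-wise equal shapes and voxel spacings equal to a relative tolerance
#' of 1e-4. Mismatched inputs are rejected — never silently resampled — with
#' an error naming both offending geometries.
#'
#' @param pet,ct [ImageVolume-class] objects with matching modalities.
#' @param mask optional `MASK` [ImageVolume-class].
#' @param center,patient metadata tags carried on the pair.
#' @return A [SamplePair-class].
#' @export
validatePair <- function(pet, ct, mask = NULL, center = "unknown",
                         patient = "unknown") {
  stopifnot(is(pet, "ImageVolume"), is(ct, "ImageVolume"))
  if (pet@modality != "PET") stop("first argument must have modality PET")
  if (ct@modality != "CT") stop("second argument must have modality CT")
  msg <- .gridMismatch(pet, ct)
  if (is.null(msg) && !is.null(mask)) msg <- .gridMismatch(pet, mask)
  if (!is.null(msg)) stop("registration error: ", msg)
  new("SamplePair", pet = pet, ct = ct, mask = mask,
      center = as.character(center), patient = as.character(patient))
}
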