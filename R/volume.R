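#' Construct an intensity volume
#'
#' @param data 3-D numeric array.
#' @param spacing voxel spacing in mm (default 0.5 isotropic).
#' @param origin world position (mm) of the centre of voxel (1,1,1); defaults
#'   to the corner voxel of the circle-of-Willis ROI grid (see [roiBox()]).
#' @return An [IntensityVolume-class] object.
#' @examples
#' v <- IntensityVolume(array(rnorm(8 * 8 * 8), c(8, 8, 8)))
#' dim(v)
#' @export
IntensityVolume <- function(data, spacing = roiSpacing(), origin = roiOrigin()) {
  storage.mode(data) <- "double"
  new("IntensityVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a vessel mask
#'
#' @param data 3-D logical (or coercible) array.
#' @inheritParams IntensityVolume
#' @return A [VesselMask-class] object.
#' @export
VesselMask <- function(data, spacing = roiSpacing(), origin = roiOrigin()) {
  d <- dim(data)
  data <- as.logical(data)
  dim(data) <- d
  new("VesselMask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @describeIn IntensityVolume the underlying 3-D array.
#' @param x,object a volume object.
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname IntensityVolume
#' @export
setMethod("volData", "Volume3D", function(x) x@data)

#' @describeIn IntensityVolume voxel spacing in mm.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname IntensityVolume
#' @export
setMethod("voxelSpacing", "Volume3D", function(x) x@spacing)

#' @describeIn IntensityVolume world position of the first voxel centre.
#' @export
setGeneric("volOrigin", function(x) standardGeneric("volOrigin"))

#' @rdname IntensityVolume
#' @export
setMethod("volOrigin", "Volume3D", function(x) x@origin)

#' @rdname IntensityVolume
#' @export
setMethod("dim", "Volume3D", function(x) dim(x@data))

setMethod("show", "IntensityVolume", function(object) {
  d <- dim(object)
  r <- range(object@data)
  cat(sprintf("IntensityVolume %d x %d x %d voxels, %.3g mm spacing\n",
              d[1], d[2], d[3], object@spacing[1]))
  cat(sprintf("  intensity range [%.4g, %.4g], origin (%.4g, %.4g, %.4g) mm\n",
              r[1], r[2], object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "VesselMask", function(object) {
  d <- dim(object)
  cat(sprintf("VesselMask %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], sum(object@data),
              100 * mean(object@data)))
})

#' Convert between world (mm) and voxel coordinates
#'
#' Voxel `i` along an axis has its centre at `origin + (i - 1) * spacing`;
#' `worldToVoxel()` returns the index of the voxel containing a world point
#' (nearest voxel centre).
#'
#' @param vol a [Volume3D-class] object.
#' @param idx n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @param mm n x 3 matrix (or length-3 vector) of world coordinates in mm.
#' @return A matrix of the converted coordinates.
#' @export
voxelToWorld <- function(vol, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx - 1, 2, voxelSpacing(vol), "*"), 2, volOrigin(vol), "+")
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(vol, mm) {
  mm <- rbind(mm)
  idx <- sweep(sweep(mm, 2, volOrigin(vol), "-"), 2, voxelSpacing(vol), "/")
  round(idx) + 1
}

#' Read and write volumes as NIfTI
#'
#' Volumes are stored as NIfTI-1 with the voxel spacing in the header and the
#' world origin in the qform/sform affine.  Masks are written as uint8.
#'
#' @param vol an [IntensityVolume-class] or [VesselMask-class].
#' @param path file path, conventionally ending in `.nii.gz`.
#' @return `readVolume()` returns an [IntensityVolume-class];
#'   `readMask()` a [VesselMask-class]; the writers return `path` invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(volData(vol) * 1)
  RNifti::pixdim(img) <- voxelSpacing(vol)
  aff <- diag(c(voxelSpacing(vol), 1))
  aff[1:3, 4] <- volOrigin(vol)
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  datatype <- if (is(vol, "VesselMask")) "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  IntensityVolume(arr, spacing = abs(diag(aff)[1:3]),
                  origin = aff[1:3, 4])
}

#' @rdname writeVolume
#' @export
readMask <- function(path) {
  v <- readVolume(path)
  VesselMask(volData(v) > 0.5, spacing = voxelSpacing(v),
             origin = volOrigin(v))
}

#' Dice overlap between two binary masks
#'
#' @param a,b [VesselMask-class] objects (or logical arrays) on the same grid.
#' @return Dice coefficient in [0, 1]; NA if both masks are empty.
#' @export
diceOverlap <- function(a, b) {
  if (is(a, "VesselMask")) a <- volData(a)
  if (is(b, "VesselMask")) b <- volData(b)
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}
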