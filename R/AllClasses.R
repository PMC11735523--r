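#' @import methods
NULL

#' Virtual base class for objects living on a regular 3-D grid
#'
#' Stores the voxel spacing (mm) and the world coordinates (mm) of the centre
#' of voxel (1,1,1).  World coordinates follow an R/A/S-style axis order so
#' that voxel index `i` along an axis maps to `origin + (i - 1) * spacing`.
#'
#' @slot spacing numeric(3), voxel spacing in mm, all positive.
#' @slot origin numeric(3), world position (mm) of the first voxel centre.
#' @keywords classes
setClass("Volume3D", representation("VIRTUAL",
  spacing = "numeric", origin = "numeric"))

setValidity("Volume3D", function(object) {
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be three positive finite numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be three finite numbers")
  TRUE
})

#' 3-D scalar intensity field
#'
#' The unit every pipeline stage consumes: a single-channel 3-D intensity
#' volume with voxel spacing and world-space origin, typically a cropped
#' circle-of-Willis region of interest on a 0.5 mm isotropic grid.
#'
#' @slot data 3-D numeric array of intensities.
#' @seealso [IntensityVolume()], [VesselMask-class]
#' @keywords classes
setClass("IntensityVolume", contains = "Volume3D",
  representation(data = "array"))

setValidity("IntensityVolume", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
  if (!is.numeric(object@data)) return("data must be numeric")
  TRUE
})

#' Binary 3-D vessel mask
#'
#' Marks segmented artery voxels on the same grid as its source volume.
#'
#' @slot data 3-D logical array.
#' @keywords classes
setClass("VesselMask", contains = "Volume3D",
  representation(data = "array"))

setValidity("VesselMask", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
  if (!is.logical(object@data)) return("data must be logical")
  TRUE
})

#' Synthetic vessel tree
#'
#' A set of centreline segments (ordered 3-D points in mm, each segment with
#' one nominal radius) forming a closed ring with outward branches, plus the
#' bifurcation points where at least three segment endpoints meet.
#'
#' @slot segments list; each element is `list(points = <n x 3 matrix>,
#'   radius = <numeric(1)>)`.
#' @slot bifurcations m x 3 numeric matrix of bifurcation points (mm).
#' @keywords classes
setClass("VesselTree", representation(
  segments = "list", bifurcations = "matrix"))

setValidity("VesselTree", function(object) {
  box <- roiBox()
  for (s in object@segments) {
    if (!is.list(s) || is.null(s$points) || is.null(s$radius))
      return("each segment needs $points and $radius")
    if (ncol(s$points) != 3L) return("segment points must be n x 3")
    if (!is.numeric(s$radius) || length(s$radius) != 1L || s$radius <= 0)
      return("segment radius must be a single positive number")
    if (any(t(s$points) < box$lower - 1e-9) ||
        any(t(s$points) > box$upper + 1e-9))
      return("centreline points must lie inside the ROI box")
  }
  TRUE
})

#' Ground truth attached to a synthetic phantom
#'
#' @slot lesions data.frame with columns `kind`, `x_mm`, `y_mm`, `z_mm`,
#'   `severity`, `size_mm`, `extent_mm` (zero rows for a healthy phantom).
#' @slot label logical(1); `TRUE` iff at least one lesion is present.
#' @slot mask [VesselMask-class] of the rasterised tree (voxels within the
#'   local radius of a centreline; narrowed by stenoses, untouched by
#'   occlusions).
#' @slot aneurysmMask logical 3-D array marking aneurysm sac voxels (all
#'   `FALSE` when no aneurysm is present).
#' @keywords classes
setClass("PhantomTruth", representation(
  lesions = "data.frame", label = "logical", mask = "VesselMask",
  aneurysmMask = "array"))

setValidity("PhantomTruth", function(object) {
  if (length(object@label) != 1L) return("label must be a single logical")
  if (!identical(object@label, nrow(object@lesions) > 0L))
    return("label must equal (number of lesions > 0)")
  TRUE
})

#' Configuration for fast fuzzy c-means segmentation
#'
#' @slot nClusters integer >= 2, number of intensity clusters (default 3:
#'   background, tissue, vessel).
#' @slot fuzziness real > 1, fuzzy exponent m (default 2).
#' @slot bins integer, number of histogram bins used when the volume has
#'   more distinct intensities than bins (default 256).
#' @slot tolerance convergence tolerance on the maximum centroid change.
#' @slot maxIterations iteration cap.
#' @slot seed integer; kept for interface symmetry (the default quantile-free
#'   initialisation is deterministic and ignores it).
#' @keywords classes
setClass("FFCMConfig", representation(
  nClusters = "integer", fuzziness = "numeric", bins = "integer",
  tolerance = "numeric", maxIterations = "integer", seed = "integer"))

setValidity("FFCMConfig", function(object) {
  if (object@nClusters < 2L) return("nClusters must be >= 2")
  if (object@fuzziness <= 1) return("fuzziness must be > 1")
  if (object@bins < 2L) return("bins must be >= 2")
  if (object@tolerance <= 0) return("tolerance must be > 0")
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  TRUE
})

#' Result of fuzzy c-means segmentation
#'
#' Memberships are computed per intensity bin and broadcast to voxels through
#' the per-voxel bin index, which keeps the object small on full-size
#' volumes; [voxelMembership()] materialises the voxel-wise matrix.
#'
#' @slot centroids sorted cluster centroid intensities.
#' @slot binCenters intensity value represented by each histogram bin.
#' @slot binMembership bins x clusters membership matrix (rows sum to 1).
#' @slot binIndex integer 3-D array mapping voxels to bins.
#' @slot labelField integer 3-D array of argmax-membership class indices.
#' @slot vesselMask [VesselMask-class]: voxels of the highest-centroid class.
#' @keywords classes
setClass("FuzzySegmentation", representation(
  centroids = "numeric", binCenters = "numeric", binMembership = "matrix",
  binIndex = "array", labelField = "array", vesselMask = "VesselMask"))

#' Stride-spaced grid of patch-classifier probabilities
#'
#' One probability per sliding-window position over an ROI.  Lattice point
#' (1,1,1) corresponds to the window whose centre voxel world position is
#' `origin`; successive lattice points are `stride * spacing` mm apart.
#'
#' @slot values 3-D numeric array of probabilities in [0, 1].
#' @slot stride window stride in voxels.
#' @slot window window edge length in voxels (32).
#' @slot spacing voxel spacing (mm) of the underlying ROI.
#' @slot origin world position (mm) of the first window centre.
#' @slot roiDim dimensions of the ROI the lattice was computed from.
#' @keywords classes
setClass("ProbabilityLattice", representation(
  values = "array", stride = "integer", window = "integer",
  spacing = "numeric", origin = "numeric", roiDim = "integer"))

setValidity("ProbabilityLattice", function(object) {
  if (length(dim(object@values)) != 3L) return("values must be a 3-D array")
  v <- object@values
  if (any(v < -1e-12 | v > 1 + 1e-12)) return("probabilities must be in [0,1]")
  expected <- (object@roiDim - object@window) %/% object@stride + 1L
  if (!identical(dim(object@values), as.integer(expected)))
    return("lattice dims must be floor((D - window)/stride) + 1 per axis")
  TRUE
})

#' Architecture configuration for the 3-D residual patch classifier
#'
#' @slot preset `"resnet50-3d"` (bottleneck stages 3-4-6-3 on 64 base
#'   channels) or `"small-3d"` (a two-stage bottleneck network on 8 base
#'   channels sized for CPU-scale phantom experiments).
#' @slot inputShape fixed to `c(32, 32, 32, 1)`.
#' @slot baseChannels stem width.
#' @slot stageBlocks bottleneck blocks per stage.
#' @slot seed integer seed fixing weight initialisation.
#' @keywords classes
setClass("ModelConfig", representation(
  preset = "character", inputShape = "integer", baseChannels = "integer",
  stageBlocks = "integer", seed = "integer"))

setValidity("ModelConfig", function(object) {
  if (!identical(object@inputShape, c(32L, 32L, 32L, 1L)))
    return("inputShape is fixed to 32 x 32 x 32 x 1")
  if (length(object@stageBlocks) < 1L) return("stageBlocks must be non-empty")
  TRUE
})

#' Training configuration for the patch classifier
#'
#' @slot maxEpochs epoch cap (default 50).
#' @slot learningRate initial Adam learning rate (default 5e-4).
#' @slot patience early-stopping patience on validation loss (default 10).
#' @slot batchSize minibatch size (default 32).
#' @slot posWeight weight multiplier on positive-class terms of the
#'   cross-entropy (default 1; set to the class ratio to re-balance).
#' @slot seed integer seed for shuffling and initial state.
#' @keywords classes
setClass("TrainConfig", representation(
  maxEpochs = "integer", learningRate = "numeric", patience = "integer",
  batchSize = "integer", posWeight = "numeric", seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@patience >= object@maxEpochs)
    return("patience must be smaller than maxEpochs")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@posWeight <= 0) return("posWeight must be > 0")
  TRUE
})

#' A trained 3-D residual patch classifier
#'
#' @slot net opaque list of layers and weights (best-validation snapshot).
#' @slot history data.frame with one row per completed epoch: train/val loss
#'   and accuracy.
#' @slot modelConfig the [ModelConfig-class] used to build the network.
#' @slot trainConfig the [TrainConfig-class] used for optimisation.
#' @keywords classes
setClass("TrainedClassifier", representation(
  net = "list", history = "data.frame", modelConfig = "ModelConfig",
  trainConfig = "TrainConfig"))

#' A collection of labelled 32^3 patches
#'
#' @slot voxels matrix with one flattened 32x32x32 patch per column.
#' @slot labels integer vector of 0/1 lesion labels.
#' @slot meta data.frame with per-patch `participant_id`, `provenance`
#'   (lesion, matched-negative, hard-negative or augmented), `x_mm`, `y_mm`,
#'   `z_mm`.
#' @keywords classes
setClass("PatchSet", representation(
  voxels = "matrix", labels = "integer", meta = "data.frame"))

setValidity("PatchSet", function(object) {
  if (nrow(object@voxels) != 32L^3)
    return("patch voxel columns must have length 32^3")
  if (ncol(object@voxels) != length(object@labels) ||
      length(object@labels) != nrow(object@meta))
    return("voxels, labels and meta must agree in length")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    return("labels must be 0 or 1")
  TRUE
})

#' Participant-level confusion counts
#'
#' @slot tp,fp,tn,fn non-negative integer counts.
#' @keywords classes
setClass("ConfusionCounts", representation(
  tp = "integer", fp = "integer", tn = "integer", fn = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(is.na(v)) || any(v < 0L)) return("counts must be non-negative")
  TRUE
})

#' Participant-level diagnostic report
#'
#' Core diagnostic fractions plus optional per-stratum sensitivities and
#' prevalence-adjusted predictive values.  Metrics with a zero denominator
#' are `NA` and listed in `undefined`; they are never silently 0.
#'
#' @slot sensitivity,specificity,accuracy,ppv,npv fractions in [0, 1] or NA.
#' @slot strata named numeric vector of per-stratum sensitivities.
#' @slot strataCounts data.frame of per-stratum detected/total counts.
#' @slot prevalence population prevalence used for adjustment (NA if unused).
#' @slot prevPPV,prevNPV prevalence-adjusted predictive values.
#' @slot undefined names of metrics whose denominator was zero.
#' @keywords classes
setClass("DiagnosticReport", representation(
  sensitivity = "numeric", specificity = "numeric", accuracy = "numeric",
  ppv = "numeric", npv = "numeric", strata = "numeric",
  strataCounts = "data.frame", prevalence = "numeric",
  prevPPV = "numeric", prevNPV = "numeric", undefined = "character"))
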