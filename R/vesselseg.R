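# Vessel segmentation by histogram-accelerated fuzzy c-means plus pruning
# of small disconnected clusters that are not arteries.

#' @rdname ffcmSegment
#' @param n_clusters number of intensity clusters (>= 2); the default 3
#'   matches the background / tissue / vessel appearance of skull-stripped
#'   angiography, with the vessel class taken as the highest centroid.
#' @param fuzziness fuzzy exponent m (> 1).
#' @param bins histogram resolution used for volumes with many distinct
#'   intensities.
#' @param tolerance convergence threshold on the maximum centroid change.
#' @param max_iterations iteration cap.
#' @param seed kept for interface symmetry; the deterministic initialisation
#'   ignores it.
#' @export
ffcmConfig <- function(n_clusters = 3L, fuzziness = 2, bins = 256L,
                       tolerance = 1e-5, max_iterations = 100L, seed = 0L) {
  new("FFCMConfig", nClusters = as.integer(n_clusters),
      fuzziness = as.numeric(fuzziness), bins = as.integer(bins),
      tolerance = as.numeric(tolerance),
      maxIterations = as.integer(max_iterations), seed = as.integer(seed))
}

#' Fast fuzzy c-means segmentation of an intensity volume
#'
#' Minimises the standard fuzzy c-means objective over the intensity
#' histogram, with each bin weighted by its voxel count, instead of over
#' individual voxels.  When the volume has no more distinct intensities than
#' `bins`, the distinct values themselves are used as bins, making the
#' result exactly equal to voxel-wise fuzzy c-means; otherwise intensities
#' are quantised into `bins` equal-width bins.  Centroids are initialised at
#' evenly spaced positions across the intensity range, which makes the
#' algorithm deterministic.  Iteration stops when the largest centroid
#' change drops below `tolerance` or after `max_iterations`.
#'
#' The vessel mask consists of the voxels whose argmax-membership class is
#' the highest-centroid cluster.
#'
#' @param volume an [IntensityVolume-class] with finite intensities.
#' @param config an [FFCMConfig-class] (see [ffcmConfig()]).
#' @return A [FuzzySegmentation-class].
#' @examples
#' v <- IntensityVolume(array(c(rep(0, 900), rep(100, 100)), c(10, 10, 10)))
#' seg <- ffcmSegment(v, ffcmConfig(n_clusters = 2))
#' centroids(seg)
#' @export
ffcmSegment <- function(volume, config = ffcmConfig()) {
  x <- as.vector(volData(volume))
  if (!length(x)) stop("volume is empty")
  if (any(!is.finite(x))) stop("volume intensities must be finite")
  rng <- range(x)
  span <- rng[2] - rng[1]
  if (span < 1e-12)
    stop("degenerate input: constant-intensity volume (centroids collide)")

  B <- config@bins
  uv <- unique(x)
  if (length(uv) <= B) {
    centers <- sort(uv)
    binIdx <- match(x, centers)
    counts <- tabulate(binIdx, length(uv))
  } else {
    w <- span / B
    binIdx <- pmin(B, as.integer(floor((x - rng[1]) / w)) + 1L)
    counts <- tabulate(binIdx, B)
    centers <- rng[1] + (seq_len(B) - 0.5) * w
  }

  K <- config@nClusters
  m <- config@fuzziness
  cent <- rng[1] + span * (2 * seq_len(K) - 1) / (2 * K)
  u <- NULL
  for (it in seq_len(config@maxIterations)) {
    d2 <- outer(centers, cent, function(a, b) (a - b)^2)
    d2 <- pmax(d2, 1e-300)
    e <- d2^(-1 / (m - 1))
    u <- e / rowSums(e)
    um <- u^m * counts
    newc <- colSums(um * centers) / colSums(um)
    delta <- max(abs(newc - cent))
    cent <- newc
    if (delta < config@tolerance) break
  }
  ord <- order(cent)
  cent <- cent[ord]
  u <- u[, ord, drop = FALSE]
  if (any(diff(cent) <= 1e-8 * span))
    stop("degenerate clustering: centroids collided during convergence")

  labBin <- max.col(u, ties.method = "first")
  lab <- labBin[binIdx]
  dim(lab) <- dim(volData(volume))
  dim(binIdx) <- dim(volData(volume))
  vm <- lab == K
  new("FuzzySegmentation", centroids = cent, binCenters = centers,
      binMembership = u, binIndex = binIdx, labelField = lab,
      vesselMask = VesselMask(vm, spacing = voxelSpacing(volume),
                              origin = volOrigin(volume)))
}

#' @describeIn ffcmSegment sorted cluster centroid intensities.
#' @param seg a [FuzzySegmentation-class].
#' @export
centroids <- function(seg) seg@centroids

#' @describeIn ffcmSegment per-voxel argmax-membership class indices.
#' @export
labelField <- function(seg) seg@labelField

#' @describeIn ffcmSegment the vessel mask (highest-centroid class).
#' @export
vesselMask <- function(seg) seg@vesselMask

#' @describeIn ffcmSegment materialise the per-voxel membership matrix
#'   (voxels x clusters; rows sum to 1).
#' @export
voxelMembership <- function(seg) {
  seg@binMembership[as.vector(seg@binIndex), , drop = FALSE]
}

setMethod("show", "FuzzySegmentation", function(object) {
  cat(sprintf("FuzzySegmentation: %d clusters, centroids %s\n",
              length(object@centroids),
              paste(sprintf("%.4g", object@centroids), collapse = ", ")))
  cat(sprintf("  vessel mask: %d voxels\n", sum(volData(object@vesselMask))))
})

#' Remove small connected clusters from a vessel mask
#'
#' Deletes every connected component with `min_voxels` voxels or fewer
#' (the threshold is inclusive: a component of exactly `min_voxels` voxels
#' is removed).  The default of 3500 voxels targets isolated non-arterial
#' clusters left by intensity clustering.
#'
#' @param mask a [VesselMask-class].
#' @param min_voxels inclusive size threshold (default 3500).
#' @param connectivity voxel adjacency: 6, 18 or 26 (default 26).
#' @return A [VesselMask-class] that is a subset of the input in which every
#'   component has more than `min_voxels` voxels.
#' @export
removeSmallClusters <- function(mask, min_voxels = 3500L, connectivity = 26L) {
  md <- volData(mask)
  labels <- cpp_label_components(as.vector(md), dim(md),
                                 as.integer(connectivity))
  ncomp <- attr(labels, "n_components")
  if (ncomp == 0L) return(mask)
  sizes <- tabulate(labels, ncomp)
  keep <- labels > 0L & sizes[pmax(labels, 1L)] > min_voxels
  dim(keep) <- dim(md)
  VesselMask(keep, spacing = voxelSpacing(mask), origin = volOrigin(mask))
}

#' Segment arteries in an intensity volume
#'
#' Composition of [ffcmSegment()] (vessel class = highest centroid) and
#' [removeSmallClusters()].
#'
#' @inheritParams ffcmSegment
#' @inheritParams removeSmallClusters
#' @return A [VesselMask-class].
#' @export
segmentVessels <- function(volume, config = ffcmConfig(),
                           min_voxels = 3500L, connectivity = 26L) {
  removeSmallClusters(vesselMask(ffcmSegment(volume, config)),
                      min_voxels = min_voxels, connectivity = connectivity)
}

#' Label connected components of a binary 3-D array
#'
#' @param mask logical 3-D array or [VesselMask-class].
#' @param connectivity 6, 18 or 26.
#' @return Integer array of component labels (0 = background) with attribute
#'   `n_components`.
#' @export
labelComponents <- function(mask, connectivity = 26L) {
  if (is(mask, "VesselMask")) mask <- volData(mask)
  labels <- cpp_label_components(as.vector(mask), dim(mask),
                                 as.integer(connectivity))
  n <- attr(labels, "n_components")
  dim(labels) <- dim(mask)
  attr(labels, "n_components") <- n
  labels
}
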