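# Sliding-window inference over the ROI and the voting rule turning patch
# probabilities into findings: threshold the stride-spaced probability
# lattice (default 0.99954) and keep connected components of at least 25
# adjacent positive window positions.

#' Lattice dimensions for a sliding window
#'
#' Window positions are origin-anchored with no padding, giving
#' `floor((D - window) / stride) + 1` positions per axis.
#'
#' @param dims ROI dimensions in voxels.
#' @param stride window stride in voxels.
#' @param window window edge length in voxels (default 32).
#' @return Integer vector of lattice dimensions.
#' @examples
#' latticeDims(c(204, 146, 156), stride = 4)   # 44 x 29 x 32
#' @export
latticeDims <- function(dims, stride, window = 32L) {
  as.integer((dims - window) %/% stride + 1L)
}

#' Sliding-window inference over an ROI
#'
#' Evaluates the patch classifier at every window position of a
#' `window`^3 window sliding with `stride` voxels through the ROI and
#' stores one probability per position.  When a vessel mask is supplied,
#' windows containing no mask voxel are skipped and scored 0 -- an
#' optimisation that leaves windows touching any vessel untouched.
#'
#' The caller is responsible for applying the same preprocessing
#' (masking, per-volume standardisation) that was used when building the
#' training patches.
#'
#' @param classifier a [TrainedClassifier-class], or a function
#'   `f(matrix of flattened windows) -> probabilities` (useful for testing).
#' @param roi an [IntensityVolume-class] at 0.5 mm spacing, at least one
#'   window large per axis.
#' @param mask optional [VesselMask-class] on the same grid.
#' @param stride window stride in voxels (>= 1, default 4).
#' @param batch windows scored per classifier call.
#' @return A [ProbabilityLattice-class].
#' @export
slideInfer <- function(classifier, roi, mask = NULL, stride = 4L,
                       batch = 128L) {
  stride <- as.integer(stride)
  stopifnot(stride >= 1L)
  d <- dim(roi)
  w <- PATCH_W
  if (any(d < w))
    stop("ROI is smaller than one ", w, "^3 window")
  ld <- latticeDims(d, stride, w)
  starts1 <- (seq_len(ld[1]) - 1L) * stride + 1L
  starts2 <- (seq_len(ld[2]) - 1L) * stride + 1L
  starts3 <- (seq_len(ld[3]) - 1L) * stride + 1L

  keep <- rep(TRUE, prod(ld))
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), d))
    p <- integral_volume(volData(mask) * 1)
    a1 <- rep(starts1, times = ld[2] * ld[3])
    a2 <- rep(rep(starts2, each = ld[1]), times = ld[3])
    a3 <- rep(starts3, each = ld[1] * ld[2])
    keep <- box_sum(p, a1, a1 + w - 1L, a2, a2 + w - 1L, a3, a3 + w - 1L) > 0
  }

  probs <- numeric(prod(ld))
  kidx <- which(keep)
  if (length(kidx)) {
    i1 <- (kidx - 1L) %% ld[1] + 1L
    i2 <- (kidx - 1L) %/% ld[1] %% ld[2] + 1L
    i3 <- (kidx - 1L) %/% (ld[1] * ld[2]) + 1L
    starts <- cbind(starts1[i1], starts2[i2], starts3[i3])

    geom <- if (is.function(classifier)) NULL else
      stem_geometry(classifier@net, w)
    if (!is.null(geom) && stride %% geom$stride == 0L) {
      # Unpadded stem: evaluate conv/bn/relu/pool once over the whole ROI,
      # then run the residual stages on exact feature-map crops.  This is
      # mathematically identical to scoring each window separately because
      # valid convolutions and aligned pooling commute with cropping.
      net <- classifier@net
      x <- matrix(as.vector(volData(roi)), ncol = 1L)
      shape <- c(d, 1L)
      for (i in seq_len(geom$n_layers)) {
        r <- layer_fwd(net$layers[[i]], x, shape, FALSE, FALSE)
        x <- r$y; shape <- r$shape
      }
      fstarts <- (starts - 1L) %/% geom$stride + 1L
      for (b0 in seq(1L, length(kidx), by = batch)) {
        bi <- b0:min(b0 + batch - 1L, length(kidx))
        Xf <- cpp_extract_windows4d(as.vector(x), shape,
                                    fstarts[bi, , drop = FALSE], geom$wf)
        fw <- net_forward(net, Xf, training = FALSE, keep_cache = FALSE,
                          from_layer = geom$n_layers + 1L,
                          in_shape = c(rep(geom$wf, 3L), geom$channels))
        probs[kidx[bi]] <- stats::plogis(fw$logits)
      }
    } else {
      vol <- as.vector(volData(roi))
      score <- if (is.function(classifier)) classifier else
        function(X) predictProbs(classifier, X, batch = batch)
      for (b0 in seq(1L, length(kidx), by = batch)) {
        bi <- b0:min(b0 + batch - 1L, length(kidx))
        X <- cpp_extract_windows(vol, d, starts[bi, , drop = FALSE], w)
        probs[kidx[bi]] <- score(X)
      }
    }
  }
  dim(probs) <- ld
  # world position of the centre voxel of the first window
  origin <- drop(voxelToWorld(roi, rep(w %/% 2L + 1L, 3L)))
  new("ProbabilityLattice", values = probs, stride = stride,
      window = w, spacing = voxelSpacing(roi), origin = origin,
      roiDim = as.integer(d))
}

#' @describeIn slideInfer probability array of a lattice.
#' @param lattice a [ProbabilityLattice-class].
#' @export
latticeValues <- function(lattice) lattice@values

#' @describeIn slideInfer world coordinates (mm) of lattice positions.
#' @param idx n x 3 matrix (or length-3 vector) of 1-based lattice indices.
#' @export
latticeToWorld <- function(lattice, idx) {
  idx <- rbind(idx)
  step <- lattice@stride * lattice@spacing
  sweep(sweep(idx - 1, 2, step, "*"), 2, lattice@origin, "+")
}

setMethod("show", "ProbabilityLattice", function(object) {
  d <- dim(object@values)
  cat(sprintf("ProbabilityLattice %d x %d x %d (stride %d, window %d)\n",
              d[1], d[2], d[3], object@stride, object@window))
  cat(sprintf("  %d positions, %d with probability > 0.5\n",
              prod(d), sum(object@values > 0.5)))
})

#' Threshold a probability lattice
#'
#' A position is positive iff its probability is greater than or equal to
#' `tau`.  The default threshold 0.99954 is the operating point of the
#' voting rule.
#'
#' @param lattice a [ProbabilityLattice-class].
#' @param tau threshold in [0, 1].
#' @return A [ProbabilityLattice-class] whose values are 0/1.
#' @export
thresholdLattice <- function(lattice, tau = 0.99954) {
  stopifnot(tau >= 0, tau <= 1)
  out <- lattice
  out@values <- (lattice@values >= tau) * 1
  out
}

#' Extract findings from a binarised lattice
#'
#' Connected components of positive lattice positions (26-adjacency by
#' default) with at least `min_support` members become findings; smaller
#' components are discarded.  The default support of 25 adjacent positive
#' predictions is the operating point of the voting rule.
#'
#' @param lattice a binarised [ProbabilityLattice-class] (see
#'   [thresholdLattice()]).
#' @param min_support minimum component size (default 25).
#' @param connectivity lattice adjacency: 6, 18 or 26 (default 26).
#' @return data.frame with one row per finding: `component_size`,
#'   `x_mm`, `y_mm`, `z_mm` (component centroid); the lattice positions of
#'   each component are in the `points` list column.
#' @export
extractFindings <- function(lattice, min_support = 25L, connectivity = 26L) {
  v <- lattice@values
  labels <- cpp_label_components(as.vector(v > 0.5), dim(v),
                                 as.integer(connectivity))
  ncomp <- attr(labels, "n_components")
  empty <- data.frame(component_size = integer(), x_mm = numeric(),
                      y_mm = numeric(), z_mm = numeric())
  empty$points <- list()
  if (ncomp == 0L) return(empty)
  sizes <- tabulate(labels, ncomp)
  keep <- which(sizes >= min_support)
  if (!length(keep)) return(empty)
  ld <- dim(v)
  rows <- lapply(keep, function(k) {
    lin <- which(labels == k)
    pts <- cbind((lin - 1L) %% ld[1] + 1L,
                 (lin - 1L) %/% ld[1] %% ld[2] + 1L,
                 (lin - 1L) %/% (ld[1] * ld[2]) + 1L)
    ctr <- latticeToWorld(lattice, colMeans(pts))
    df <- data.frame(component_size = sizes[k], x_mm = ctr[1],
                     y_mm = ctr[2], z_mm = ctr[3])
    df$points <- list(pts)
    df
  })
  out <- do.call(rbind, rows)
  out[order(-out$component_size), , drop = FALSE]
}

#' Participant-level decision
#'
#' A participant is called positive iff at least one finding survives the
#' voting rule.  The decision is invariant to the order of findings.
#'
#' @param findings data.frame from [extractFindings()].
#' @return Single logical.
#' @export
participantDecision <- function(findings) {
  nrow(findings) > 0L
}
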