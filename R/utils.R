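# Internal helpers shared across modules.

# Run `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a bounded child seed from a base seed and a small offset; keeps all
# seeds well inside the 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483587)
}

#' Region-of-interest geometry
#'
#' The pipeline operates on a fixed cropped region of interest: a
#' 102 x 73 x 78 mm box centred at (0, 3, -33) mm in an MNI-like space,
#' covering the circle of Willis and the major arteries branching from it,
#' sampled on a 0.5 mm isotropic grid of 204 x 146 x 156 voxels.
#'
#' @return `roiBox()` returns `list(lower, upper, center)` in mm;
#'   `roiDim()` the grid dimensions; `roiSpacing()` the voxel spacing; and
#'   `roiOrigin()` the world position of the first voxel centre.
#' @examples
#' roiDim()
#' roiBox()$lower
#' @export
roiBox <- function() {
  center <- c(0, 3, -33)
  half <- c(102, 73, 78) / 2
  list(lower = center - half, upper = center + half, center = center)
}

#' @rdname roiBox
#' @export
roiDim <- function() c(204L, 146L, 156L)

#' @rdname roiBox
#' @export
roiSpacing <- function() c(0.5, 0.5, 0.5)

#' @rdname roiBox
#' @export
roiOrigin <- function() roiBox()$lower + roiSpacing() / 2

# 3-D summed-volume table with a zero-padded leading plane, so that
# box sums can be taken by 8-term inclusion-exclusion.
integral_volume <- function(x) {
  d <- dim(x)
  cs <- apply(x, c(2, 3), cumsum)
  cs <- aperm(apply(cs, c(1, 3), cumsum), c(2, 1, 3))
  cs <- aperm(apply(cs, c(1, 2), cumsum), c(2, 3, 1))
  p <- array(0, d + 1L)
  p[-1L, -1L, -1L] <- cs
  p
}

# Sum of x over the inclusive index box [a1..b1, a2..b2, a3..b3] given the
# padded integral volume p (vectorised over equal-length index vectors).
box_sum <- function(p, a1, b1, a2, b2, a3, b3) {
  d <- dim(p)
  idx <- function(i, j, k) i + d[1] * (j - 1 + d[2] * (k - 1))
  p[idx(b1 + 1L, b2 + 1L, b3 + 1L)] -
    p[idx(a1, b2 + 1L, b3 + 1L)] -
    p[idx(b1 + 1L, a2, b3 + 1L)] -
    p[idx(b1 + 1L, b2 + 1L, a3)] +
    p[idx(a1, a2, b3 + 1L)] +
    p[idx(a1, b2 + 1L, a3)] +
    p[idx(b1 + 1L, a2, a3)] -
    p[idx(a1, a2, a3)]
}

# Content hash of an arbitrary R object (used to stamp pipeline artifacts).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
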