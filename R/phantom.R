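# Synthetic vascular phantoms: bright tubular vessels on darker tissue in
# the circle-of-Willis ROI, with optional stenoses (focal diameter
# reduction >= 50%), occlusions (flow-void signal gaps) and saccular
# aneurysms (>= 2 mm sacs tangent to the vessel wall).

PHANTOM_TISSUE <- 0.25
PHANTOM_VESSEL <- 1.00

#' Generate a synthetic vessel tree
#'
#' Builds a closed, ring-like arterial structure (an idealised circle of
#' Willis) in the ROI box with `2 * complexity` outward branches.  Each
#' branch root splits the ring, so the root is shared by two ring arcs and
#' the branch itself and is recorded as a bifurcation point.  Centreline
#' geometry is randomised but fully determined by `seed`.
#'
#' @param seed integer seed; identical seeds give bitwise-identical trees.
#' @param complexity small positive integer scaling the number of branches
#'   (values below 1 are clamped to 1).
#' @return A [VesselTree-class] with all centreline points inside the ROI
#'   box and nominal radii in [1, 3] mm.
#' @examples
#' tree <- generateVesselTree(seed = 1, complexity = 2)
#' length(tree@segments)
#' @export
generateVesselTree <- function(seed, complexity = 2L) {
  complexity <- max(1L, as.integer(complexity))
  with_seed(seed, {
    box <- roiBox()
    margin <- 4
    lo <- box$lower + margin
    hi <- box$upper - margin
    ctr <- box$center
    nb <- 2L * complexity

    gap <- 2 * pi / nb
    ang <- sort((seq_len(nb) - 1) * gap + stats::runif(nb, 0.1 * gap, 0.9 * gap))
    a <- stats::runif(1, 12, 15)      # ring semi-axis, x (mm)
    b <- stats::runif(1, 9, 11)       # ring semi-axis, y (mm)
    zamp <- stats::runif(1, 1, 3)     # out-of-plane modulation (mm)
    ringpt <- function(t) cbind(ctr[1] + a * cos(t),
                                ctr[2] + b * sin(t),
                                ctr[3] + zamp * sin(2 * t))

    segments <- vector("list", 0L)
    for (i in seq_len(nb)) {
      t0 <- ang[i]
      t1 <- if (i < nb) ang[i + 1] else ang[1] + 2 * pi
      ts <- seq(t0, t1, length.out = max(4L, ceiling((t1 - t0) * 12)))
      segments[[length(segments) + 1L]] <-
        list(points = ringpt(ts), radius = stats::runif(1, 1.8, 2.5),
             kind = "ring")
    }
    bif <- ringpt(ang)

    for (i in seq_len(nb)) {
      p0 <- bif[i, ]
      radial <- c(a * cos(ang[i]), b * sin(ang[i]), 0)
      radial <- radial / sqrt(sum(radial^2))
      d <- radial + c(0, 0, stats::runif(1, -0.8, 0.8))
      d <- d / sqrt(sum(d^2))
      len <- stats::runif(1, 18, 30)
      perp <- c(-d[2], d[1], stats::runif(1, -0.3, 0.3))
      perp <- perp / sqrt(sum(perp^2))
      bend <- stats::runif(1, -5, 5)
      c1 <- p0 + d * len / 2 + perp * bend
      c2 <- p0 + d * len
      ts <- seq(0, 1, length.out = max(6L, ceiling(len / 1.5)))
      pts <- sapply(1:3, function(j)
        (1 - ts)^2 * p0[j] + 2 * ts * (1 - ts) * c1[j] + ts^2 * c2[j])
      inside <- apply(pts, 1L, function(p) all(p >= lo) && all(p <= hi))
      keep <- if (all(inside)) length(ts) else max(2L, which(!inside)[1] - 1L)
      segments[[length(segments) + 1L]] <-
        list(points = pts[seq_len(keep), , drop = FALSE],
             radius = stats::runif(1, 1.4, 2.2), kind = "branch")
    }
    new("VesselTree", segments = segments, bifurcations = bif)
  })
}

#' @describeIn generateVesselTree bifurcation points (m x 3 matrix, mm).
#' @param tree a [VesselTree-class].
#' @export
treeBifurcations <- function(tree) tree@bifurcations

#' @describeIn generateVesselTree hard-negative training sites of a tree:
#'   its bifurcation points, one random interior centreline point per
#'   segment, and the distal tip of every branch -- the lesion-free
#'   locations that most resemble lesions and are oversampled so the
#'   classifier learns their normal appearance.
#' @param site_seed integer seed for the interior-point draws.
#' @export
treeHardNegativeSites <- function(tree, site_seed = 0L) {
  pts <- list(tree@bifurcations)
  with_seed(site_seed, {
    for (s in tree@segments) {
      n <- nrow(s$points)
      j <- sample(seq(max(2L, ceiling(0.25 * n)),
                      min(n - 1L, floor(0.75 * n))), 1L)
      pts[[length(pts) + 1L]] <- s$points[j, , drop = FALSE]
      if (identical(s$kind, "branch"))
        pts[[length(pts) + 1L]] <- s$points[n, , drop = FALSE]
    }
  })
  do.call(rbind, pts)
}

#' @describeIn generateVesselTree list of centreline segments.
#' @export
treeSegments <- function(tree) tree@segments

setMethod("show", "VesselTree", function(object) {
  cat(sprintf("VesselTree: %d segments, %d bifurcations, radii %.2f-%.2f mm\n",
              length(object@segments), nrow(object@bifurcations),
              min(vapply(object@segments, `[[`, 1, "radius")),
              max(vapply(object@segments, `[[`, 1, "radius"))))
})

#' Build a lesion specification table
#'
#' @param kind one of `"stenosis"`, `"occlusion"`, `"aneurysm"`.
#' @param center length-3 world coordinates (mm) on (within one radius of) a
#'   vessel centreline.
#' @param severity diameter-reduction fraction; in [0.5, 1) for stenosis and
#'   exactly 1 for occlusion.
#' @param size_mm sac diameter (>= 2 mm) for aneurysms.
#' @param extent_mm along-centreline length (mm) affected by a stenosis or
#'   occlusion.
#' @return A one-row data.frame in the lesion-table layout used throughout
#'   the package (`kind`, `x_mm`, `y_mm`, `z_mm`, `severity`, `size_mm`,
#'   `extent_mm`).
#' @export
lesionSpec <- function(kind = c("stenosis", "occlusion", "aneurysm"),
                       center, severity = NA_real_, size_mm = NA_real_,
                       extent_mm = NA_real_) {
  kind <- match.arg(kind)
  if (kind == "stenosis" &&
      (is.na(severity) || severity < 0.5 || severity >= 1))
    stop("stenosis severity must lie in [0.5, 1)")
  if (kind == "occlusion") {
    if (is.na(severity)) severity <- 1
    if (severity != 1) stop("occlusion severity must be exactly 1")
  }
  if (kind == "aneurysm" && (is.na(size_mm) || size_mm < 2))
    stop("aneurysm size_mm must be >= 2 mm")
  if (kind != "aneurysm" && (is.na(extent_mm) || extent_mm <= 0))
    stop("stenosis/occlusion needs a positive extent_mm")
  data.frame(kind = kind, x_mm = center[1], y_mm = center[2],
             z_mm = center[3], severity = severity, size_mm = size_mm,
             extent_mm = extent_mm, stringsAsFactors = FALSE)
}

# Collect voxel indices inside a capsule around edge p1-p2 with linearly
# interpolated radii r1, r2.
capsule_voxels <- function(p1, p2, r1, r2, dims, origin, sp) {
  rmax <- max(r1, r2)
  lo <- pmin(p1, p2) - rmax - sp
  hi <- pmax(p1, p2) + rmax + sp
  i0 <- pmax(1L, as.integer(floor((lo - origin) / sp)) + 1L)
  i1 <- pmin(dims, as.integer(ceiling((hi - origin) / sp)) + 1L)
  if (any(i0 > i1)) return(integer(0))
  ii <- i0[1]:i1[1]; jj <- i0[2]:i1[2]; kk <- i0[3]:i1[3]
  nx <- length(ii); ny <- length(jj); nz <- length(kk)
  X <- rep(origin[1] + (ii - 1) * sp, times = ny * nz)
  Y <- rep(rep(origin[2] + (jj - 1) * sp, each = nx), times = nz)
  Z <- rep(origin[3] + (kk - 1) * sp, each = nx * ny)
  d <- p2 - p1
  L2 <- sum(d^2)
  if (L2 < 1e-12) {
    t <- 0
  } else {
    t <- ((X - p1[1]) * d[1] + (Y - p1[2]) * d[2] + (Z - p1[3]) * d[3]) / L2
    t <- pmin(1, pmax(0, t))
  }
  rx <- r1 + t * (r2 - r1)
  dist2 <- (X - (p1[1] + t * d[1]))^2 + (Y - (p1[2] + t * d[2]))^2 +
    (Z - (p1[3] + t * d[3]))^2
  inside <- dist2 <= rx^2
  if (!any(inside)) return(integer(0))
  IX <- rep(ii, times = ny * nz)
  IY <- rep(rep(jj, each = nx), times = nz)
  IZ <- rep(kk, each = nx * ny)
  (IX + (IY - 1L) * dims[1] + (IZ - 1L) * dims[1] * dims[2])[inside]
}

sphere_voxels <- function(center, radius, dims, origin, sp) {
  capsule_voxels(center, center, radius, radius, dims, origin, sp)
}

# Cumulative arclength of a polyline (n x 3).
polyline_arclength <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

# Locate the segment and point index nearest to a world coordinate.
nearest_centerline_point <- function(tree, center) {
  best <- list(dist = Inf, seg = NA_integer_, idx = NA_integer_)
  for (s in seq_along(tree@segments)) {
    pts <- tree@segments[[s]]$points
    d <- sqrt(colSums((t(pts) - center)^2))
    j <- which.min(d)
    if (d[j] < best$dist) best <- list(dist = d[j], seg = s, idx = j)
  }
  best
}

#' Rasterise a vessel tree and its lesions into an intensity volume
#'
#' Produces a 204 x 146 x 156 voxel volume on the 0.5 mm isotropic ROI grid.
#' Vessel voxels (those within the local radius of a centreline) take the
#' flow-signal intensity, which is four times the tissue intensity before
#' noise.  A stenosis scales the local radius by `(1 - severity)` over
#' `extent_mm`; an occlusion leaves the geometry but resets the signal to
#' tissue level over `extent_mm` (emulating a flow void); an aneurysm adds a
#' bright sphere of diameter `size_mm` tangent to the vessel wall.  Gaussian
#' noise with standard deviation `noise_sd` (in units of the vessel signal)
#' is added everywhere.
#'
#' @param tree a [VesselTree-class].
#' @param lesions lesion table as produced by [lesionSpec()] (possibly
#'   rbind-ed); `NULL` for a healthy phantom.
#' @param noise_sd non-negative noise standard deviation; the default 0.1 is
#'   a tenth of the vessel signal.
#' @param seed integer seed controlling the noise draw.
#' @return `list(volume = IntensityVolume, truth = PhantomTruth)`.
#' @examples
#' tree <- generateVesselTree(1)
#' ph <- rasterizePhantom(tree, noise_sd = 0, seed = 1)
#' sort(unique(as.vector(volData(ph$volume))))
#' @export
rasterizePhantom <- function(tree, lesions = NULL, noise_sd = 0.1, seed = 0L) {
  stopifnot(noise_sd >= 0)
  dims <- roiDim()
  sp <- roiSpacing()
  origin <- roiOrigin()
  if (is.null(lesions)) {
    lesions <- data.frame(kind = character(), x_mm = numeric(),
                          y_mm = numeric(), z_mm = numeric(),
                          severity = numeric(), size_mm = numeric(),
                          extent_mm = numeric(), stringsAsFactors = FALSE)
  }

  # Per-segment point radii, modified by stenoses; occlusion stretches and
  # aneurysm spheres recorded separately.
  radii <- lapply(tree@segments, function(s) rep(s$radius, nrow(s$points)))
  occl <- lapply(tree@segments, function(s) logical(nrow(s$points)))
  spheres <- list()

  for (li in seq_len(nrow(lesions))) {
    les <- lesions[li, ]
    center <- c(les$x_mm, les$y_mm, les$z_mm)
    hit <- nearest_centerline_point(tree, center)
    if (hit$dist > tree@segments[[hit$seg]]$radius)
      stop(sprintf("lesion %d (%s): center is not on the vessel tree", li,
                   les$kind))
    pts <- tree@segments[[hit$seg]]$points
    if (les$kind %in% c("stenosis", "occlusion")) {
      arc <- polyline_arclength(pts)
      sel <- abs(arc - arc[hit$idx]) <= les$extent_mm / 2
      if (les$kind == "stenosis") {
        radii[[hit$seg]][sel] <- radii[[hit$seg]][sel] * (1 - les$severity)
      } else {
        occl[[hit$seg]][sel] <- TRUE
      }
    } else {
      tangent <- if (hit$idx < nrow(pts)) {
        pts[hit$idx + 1L, ] - pts[hit$idx, ]
      } else {
        pts[hit$idx, ] - pts[hit$idx - 1L, ]
      }
      tangent <- tangent / sqrt(sum(tangent^2))
      u <- c(tangent[2], -tangent[1], 0)
      if (sum(u^2) < 1e-8) u <- c(1, 0, 0)
      u <- u / sqrt(sum(u^2))
      r <- tree@segments[[hit$seg]]$radius
      spheres[[length(spheres) + 1L]] <-
        list(center = pts[hit$idx, ] + u * (r + les$size_mm / 2),
             radius = les$size_mm / 2)
    }
  }

  nvox <- prod(dims)
  mask <- logical(nvox)
  occl_vox <- logical(nvox)
  for (s in seq_along(tree@segments)) {
    pts <- tree@segments[[s]]$points
    r <- radii[[s]]
    o <- occl[[s]]
    for (e in seq_len(nrow(pts) - 1L)) {
      if (r[e] <= 0 && r[e + 1L] <= 0) next
      idx <- capsule_voxels(pts[e, ], pts[e + 1L, ], r[e], r[e + 1L],
                            dims, origin, sp[1])
      mask[idx] <- TRUE
      if (o[e] && o[e + 1L]) occl_vox[idx] <- TRUE
    }
  }
  sac <- logical(nvox)
  for (sph in spheres)
    sac[sphere_voxels(sph$center, sph$radius, dims, origin, sp[1])] <- TRUE

  bright <- (mask & !occl_vox) | sac
  vol <- rep(PHANTOM_TISSUE, nvox)
  vol[bright] <- PHANTOM_VESSEL
  if (noise_sd > 0)
    vol <- vol + with_seed(seed, stats::rnorm(nvox, 0, noise_sd))
  dim(vol) <- dims
  dim(mask) <- dims
  dim(sac) <- dims

  truth <- new("PhantomTruth", lesions = lesions,
               label = nrow(lesions) > 0L,
               mask = VesselMask(mask), aneurysmMask = sac)
  list(volume = IntensityVolume(vol), truth = truth)
}

#' @describeIn rasterizePhantom lesion table of a [PhantomTruth-class].
#' @param truth a [PhantomTruth-class].
#' @export
lesionTable <- function(truth) truth@lesions

#' @describeIn rasterizePhantom participant-level binary label.
#' @export
participantLabel <- function(truth) truth@label

#' @describeIn rasterizePhantom noise-free vessel mask of the phantom.
#' @export
truthMask <- function(truth) truth@mask

# Draw a lesion for one participant: a site on a sufficiently thick segment
# away from the segment ends.  Must be called inside a seeded context.
draw_lesion <- function(tree, kind, exclude = integer(0)) {
  segs <- tree@segments
  thick <- which(vapply(segs, `[[`, 1, "radius") >= 1.6 &
                 vapply(segs, function(s) nrow(s$points), 1L) >= 6L)
  thick <- setdiff(thick, exclude)
  if (!length(thick)) thick <- setdiff(seq_along(segs), exclude)
  if (!length(thick)) thick <- seq_along(segs)
  s <- if (length(thick) == 1L) thick else sample(thick, 1L)
  pts <- segs[[s]]$points
  n <- nrow(pts)
  j <- sample(seq(max(2L, ceiling(0.25 * n)), min(n - 1L, floor(0.75 * n))), 1L)
  center <- pts[j, ]
  spec <- switch(kind,
    stenosis = lesionSpec("stenosis", center,
                          severity = stats::runif(1, 0.5, 0.7),
                          extent_mm = stats::runif(1, 5, 8)),
    occlusion = lesionSpec("occlusion", center, severity = 1,
                           extent_mm = stats::runif(1, 5, 8)),
    aneurysm = lesionSpec("aneurysm", center,
                          size_mm = stats::runif(1, 2.5, 5)))
  attr(spec, "segment") <- s
  spec
}

# Lesion multiplicity of an affected participant: 1 or 2, with the second
# lesion on a different segment.  The 40% chance of a second lesion matches
# the lesion-per-affected-participant ratio of the population cohorts this
# pipeline emulates (~1.4).
draw_participant_lesions <- function(tree, kind) {
  first <- draw_lesion(tree, kind)
  if (stats::runif(1) < 0.405) {
    second <- draw_lesion(tree, kind,
                          exclude = attr(first, "segment"))
    out <- rbind(first, second)
  } else {
    out <- first
  }
  attr(out, "segment") <- NULL
  out
}

#' Generate a cohort of synthetic phantoms
#'
#' `round(n * prevalence)` participants (round-half-up) carry exactly one
#' lesion each, with lesion kinds drawn from `lesion_mix`.  With an
#' `out_dir`, volumes are written as NIfTI (`.nii.gz`) and three TSV tables
#' are written alongside: `truth.tsv` (one row per lesion), `sites.tsv`
#' (per-participant bifurcation points, the hard-negative sites) and
#' `manifest.tsv` (participant id, file, label, per-participant seeds).
#'
#' @param n cohort size (> 0).
#' @param prevalence fraction of participants with a lesion, in [0, 1].
#' @param lesion_mix named fractions over `stenosis`, `occlusion`,
#'   `aneurysm`; must sum to 1.
#' @param noise_sd noise level passed to [rasterizePhantom()].
#' @param seed integer master seed; the whole cohort is deterministic in it.
#' @param out_dir output directory (created if missing); when `NULL`
#'   volumes are kept in memory (only sensible for small `n`).
#' @param complexity passed to [generateVesselTree()].
#' @param render rasterise the volumes (default). With `render = FALSE`
#'   only the manifest, truth and site tables are produced -- handy when
#'   just the cohort composition is needed.
#' @return A list of class `phantom_cohort` with elements `manifest`
#'   (data.frame), `truth` (lesion table), `sites` (hard-negative sites),
#'   `dir` (or `NULL`) and, for in-memory cohorts, `volumes` and `truths`.
#' @export
makeCohort <- function(n, prevalence, lesion_mix = c(stenosis = 1),
                       noise_sd = 0.1, seed = 1L, out_dir = NULL,
                       complexity = 2L, render = TRUE) {
  if (n <= 0) stop("n must be positive")
  if (prevalence < 0 || prevalence > 1) stop("prevalence must be in [0, 1]")
  if (abs(sum(lesion_mix) - 1) > 1e-8)
    stop("lesion_mix fractions must sum to 1")
  n <- as.integer(n)
  k <- as.integer(floor(n * prevalence + 0.5))   # round-half-up

  draws <- with_seed(seed, {
    list(lesioned = sort(sample.int(n, k)),
         kinds = sample(names(lesion_mix), n, replace = TRUE,
                        prob = lesion_mix),
         tree_seeds = sample.int(2147483000L, n),
         noise_seeds = sample.int(2147483000L, n),
         lesion_seeds = sample.int(2147483000L, n),
         site_seeds = sample.int(2147483000L, n))
  })

  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  ids <- sprintf("P%03d", seq_len(n))
  manifest <- data.frame(participant_id = ids, file = NA_character_,
                         label = seq_len(n) %in% draws$lesioned,
                         tree_seed = draws$tree_seeds,
                         stringsAsFactors = FALSE)
  truth_rows <- list()
  site_rows <- list()
  volumes <- if (is.null(out_dir)) vector("list", n) else NULL
  truths <- if (is.null(out_dir)) vector("list", n) else NULL

  for (i in seq_len(n)) {
    tree <- generateVesselTree(draws$tree_seeds[i], complexity)
    les <- NULL
    if (manifest$label[i]) {
      les <- with_seed(draws$lesion_seeds[i],
                       draw_participant_lesions(tree, draws$kinds[i]))
    }
    ph <- if (render) rasterizePhantom(tree, les, noise_sd = noise_sd,
                                       seed = draws$noise_seeds[i]) else NULL
    if (!is.null(les)) {
      truth_rows[[length(truth_rows) + 1L]] <-
        cbind(participant_id = ids[i], les)
    }
    hns <- treeHardNegativeSites(tree, draws$site_seeds[i])
    site_rows[[length(site_rows) + 1L]] <-
      data.frame(participant_id = ids[i], x_mm = hns[, 1], y_mm = hns[, 2],
                 z_mm = hns[, 3], stringsAsFactors = FALSE)
    if (!is.null(ph)) {
      if (is.null(out_dir)) {
        volumes[[i]] <- ph$volume
        truths[[i]] <- ph$truth
      } else {
        f <- file.path(out_dir, paste0(ids[i], ".nii.gz"))
        writeVolume(ph$volume, f)
        manifest$file[i] <- f
      }
    }
  }

  empty_truth <- data.frame(participant_id = character(), kind = character(),
                            x_mm = numeric(), y_mm = numeric(),
                            z_mm = numeric(), severity = numeric(),
                            size_mm = numeric(), extent_mm = numeric(),
                            stringsAsFactors = FALSE)
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else empty_truth
  sites <- do.call(rbind, site_rows)
  if (!is.null(out_dir)) {
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sites, file.path(out_dir, "sites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(manifest = manifest, truth = truth, sites = sites,
                 dir = out_dir, volumes = volumes, truths = truths),
            class = "phantom_cohort")
}

#' @describeIn makeCohort load one participant's volume from a cohort.
#' @param cohort a `phantom_cohort`.
#' @param id participant identifier.
#' @export
cohortVolume <- function(cohort, id) {
  i <- match(id, cohort$manifest$participant_id)
  if (is.na(i)) stop("unknown participant: ", id)
  if (!is.null(cohort$volumes)) return(cohort$volumes[[i]])
  readVolume(cohort$manifest$file[i])
}

#' @describeIn makeCohort read a cohort written by `makeCohort(out_dir=)`.
#' @param dir cohort directory.
#' @export
readCohort <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  sites <- utils::read.table(file.path(dir, "sites.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  structure(list(manifest = manifest, truth = truth, sites = sites,
                 dir = dir, volumes = NULL, truths = NULL),
            class = "phantom_cohort")
}
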