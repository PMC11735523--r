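# Extraction, augmentation and assembly of labelled 32^3-voxel patches with
# class-ratio control, hard-negative oversampling and participant-level
# splits.

PATCH_W <- 32L

#' Extract a 32^3-voxel patch centred on a world coordinate
#'
#' The patch covers 16 x 16 x 16 mm at 0.5 mm spacing.  Its centre voxel is
#' the voxel containing `center_mm` (indices `c - 16 .. c + 15` per axis);
#' voxels outside the volume are zero-filled, zero being the background
#' value of skull-stripped angiography.
#'
#' @param volume an [IntensityVolume-class].
#' @param center_mm length-3 world coordinate inside the volume.
#' @return A 32 x 32 x 32 numeric array.
#' @export
extractPatch <- function(volume, center_mm) {
  idx <- drop(worldToVoxel(volume, center_mm))
  d <- dim(volume)
  if (any(idx < 1) || any(idx > d))
    stop("patch center lies outside the volume")
  starts <- matrix(as.integer(idx - PATCH_W / 2L), 1L, 3L)
  p <- cpp_extract_windows(as.vector(volData(volume)), d, starts, PATCH_W)
  array(p[, 1L], rep(PATCH_W, 3L))
}

flip_patch <- function(p, f) {
  if (f[1]) p <- p[PATCH_W:1, , , drop = FALSE]
  if (f[2]) p <- p[, PATCH_W:1, , drop = FALSE]
  if (f[3]) p <- p[, , PATCH_W:1, drop = FALSE]
  p
}

all_flips <- function() as.matrix(expand.grid(x = c(FALSE, TRUE),
                                              y = c(FALSE, TRUE),
                                              z = c(FALSE, TRUE)))

#' Enumerate flip/offset augmentations of a patch
#'
#' Produces all eight axis-flip orientations of `1 + n_offsets` re-centred
#' copies of the patch at `center_mm`.  Offsets are integer-voxel
#' translations of the extraction centre, drawn per axis uniformly with
#' magnitude at most `max_offset_mm` (8 voxels at 0.5 mm spacing for the
#' default 4 mm) and applied before flipping, so no interpolation occurs.
#' The identity member (no flip, zero offset) is always first, and labels
#' are preserved.
#'
#' @inheritParams extractPatch
#' @param label binary lesion label attached to every member.
#' @param max_offset_mm maximum per-axis offset in mm (>= 0).
#' @param n_offsets number of random offset draws in addition to the
#'   centred copy.
#' @param seed integer seed making the offset draws deterministic.
#' @return A list of `8 * (1 + n_offsets)` elements, each
#'   `list(voxels, label, center_mm, flip, offset_vox)`.
#' @export
enumerateAugmentations <- function(volume, center_mm, label = 1L,
                                   max_offset_mm = 4, n_offsets = 0L,
                                   seed = 0L) {
  stopifnot(max_offset_mm >= 0, n_offsets >= 0)
  kmax <- as.integer(floor(max_offset_mm / voxelSpacing(volume)[1]))
  offsets <- matrix(0L, 1L, 3L)
  if (n_offsets > 0L) {
    draws <- with_seed(seed, matrix(
      as.integer(sample(seq(-kmax, kmax), 3L * n_offsets, replace = TRUE)),
      ncol = 3L))
    offsets <- rbind(offsets, draws)
  }
  flips <- all_flips()
  out <- vector("list", 8L * nrow(offsets))
  n <- 0L
  for (oi in seq_len(nrow(offsets))) {
    ctr <- center_mm + offsets[oi, ] * voxelSpacing(volume)
    base <- extractPatch(volume, ctr)
    for (fi in seq_len(nrow(flips))) {
      n <- n + 1L
      out[[n]] <- list(voxels = flip_patch(base, flips[fi, ]),
                       label = as.integer(label), center_mm = ctr,
                       flip = flips[fi, ], offset_vox = offsets[oi, ])
    }
  }
  out
}

#' Split participants into train/validation/test sets
#'
#' Participants are shuffled by `seed` and partitioned by count using
#' largest-remainder rounding of the requested fractions, so each bucket
#' deviates from its exact share by less than one participant.
#'
#' @param ids unique participant identifiers (at least 3).
#' @param fractions train/val/test fractions summing to 1
#'   (default 0.80/0.05/0.15).
#' @param seed integer seed.
#' @return data.frame with columns `participant_id` and `split`.
#' @examples
#' table(splitParticipants(sprintf("P%03d", 1:100), seed = 1)$split)
#' @export
splitParticipants <- function(ids, fractions = c(train = 0.80, val = 0.05,
                                                 test = 0.15), seed = 1L) {
  if (anyDuplicated(ids)) stop("participant ids must be unique")
  if (length(ids) < 3L) stop("need at least 3 participants to split")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- length(ids)
  shuffled <- with_seed(seed, sample(ids))
  exact <- n * fractions
  sizes <- floor(exact)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(exact - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  split <- rep(c("train", "val", "test"), times = sizes)
  data.frame(participant_id = shuffled, split = split,
             stringsAsFactors = FALSE)[order(match(shuffled, ids)), ,
                                       drop = FALSE]
}

#' Patch sampling plan
#'
#' Captures the class-ratio and augmentation policy used when assembling
#' training data: a negatives-to-positives ratio of 4:1 for aneurysms and
#' 5:1 for stenosis in the training split, an exact 1:1 ratio in validation
#' and test, matched negatives taken at lesion coordinates from lesion-free
#' participants, and hard negatives at arterial bifurcation sites.
#'
#' @param mode `"stenosis"` or `"aneurysm"`; sets the default ratio.
#' @param ratio negatives per positive in the training split.
#' @param n_healthy cap on the number of lesion-free participants drawn on
#'   (default 400).
#' @param max_offset_mm,n_offsets augmentation policy, see
#'   [enumerateAugmentations()].
#' @param seed integer seed controlling sampling.
#' @return A list of class `sampling_plan`.
#' @export
samplingPlan <- function(mode = c("stenosis", "aneurysm"), ratio = NULL,
                         n_healthy = 400L, max_offset_mm = 4,
                         n_offsets = 1L, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(ratio)) ratio <- if (mode == "aneurysm") 4L else 5L
  if (ratio < 1L) stop("ratio must be >= 1")
  structure(list(mode = mode, ratio = as.integer(ratio),
                 n_healthy = as.integer(n_healthy),
                 max_offset_mm = max_offset_mm,
                 n_offsets = as.integer(n_offsets),
                 seed = as.integer(seed)),
            class = "sampling_plan")
}

new_patch_set <- function(voxels, labels, meta) {
  new("PatchSet", voxels = voxels, labels = as.integer(labels), meta = meta)
}

#' @describeIn buildTrainingSet number of patches in a [PatchSet-class].
#' @param x a `PatchSet`.
#' @export
setMethod("length", "PatchSet", function(x) length(x@labels))

#' @describeIn buildTrainingSet patch voxel matrix (32^3 rows, one patch
#'   per column).
#' @export
patchVoxels <- function(x) x@voxels

#' @describeIn buildTrainingSet integer 0/1 labels.
#' @export
patchLabels <- function(x) x@labels

#' @describeIn buildTrainingSet per-patch metadata.
#' @export
patchMeta <- function(x) x@meta

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: %d patches (%d positive / %d negative)\n",
              length(object@labels), sum(object@labels == 1L),
              sum(object@labels == 0L)))
  if (nrow(object@meta))
    print(table(object@meta$provenance))
})

#' Assemble labelled patch sets for training, validation and test
#'
#' Positives are lesion-centred patches; in the training split each one is
#' expanded by flip/offset augmentation.  Negatives come from lesion-free
#' participants only, at (i) the lesion coordinates observed anywhere in the
#' cohort (matched negatives) and (ii) each participant's arterial
#' bifurcation sites (hard negatives), combined to reach
#' `ratio` negatives per positive in the training split and exactly 1:1 in
#' validation and test.  When the training split needs more negatives than
#' there are distinct sites, sites are recycled through flip (and then
#' offset) augmentation; if even that cannot meet the ratio, or a 1:1
#' validation/test split cannot be filled, an error reports the shortfall.
#' No participant contributes to more than one split.
#'
#' @param cohort a `phantom_cohort` (see [makeCohort()] / [readCohort()]).
#' @param plan a [samplingPlan()].
#' @param split a split table from [splitParticipants()].
#' @param preprocess function `(volume, participant_id) -> volume` applied
#'   before patch extraction (e.g. vessel masking and per-volume
#'   standardisation); defaults to identity.
#' @return Named list of [PatchSet-class] objects (`train`, `val`, `test`).
#' @export
buildTrainingSet <- function(cohort, plan, split, preprocess = NULL) {
  if (is.null(preprocess)) preprocess <- function(v, id) v
  manifest <- merge(cohort$manifest, split, by = "participant_id")
  truth <- cohort$truth
  if (!nrow(truth)) stop("cohort contains no lesions; nothing to learn")
  lesion_coords <- truth[, c("x_mm", "y_mm", "z_mm")]

  out <- list()
  for (s in c("train", "val", "test")) {
    part <- manifest[manifest$split == s, , drop = FALSE]
    lesioned <- part$participant_id[part$label]
    healthy <- part$participant_id[!part$label]
    if (length(healthy) > plan$n_healthy)
      healthy <- with_seed(child_seed(plan$seed, 7L),
                           sample(healthy, plan$n_healthy))

    # patch counts are known in advance, so the voxel matrix is allocated
    # once and filled in place (patch sets get large at full cohort size)
    n_lesions <- vapply(lesioned, function(id)
      sum(truth$participant_id == id), 0L)
    n_variant <- 8L * (1L + plan$n_offsets)
    n_pos <- sum(n_lesions) * (if (s == "train") n_variant else 1L)
    need <- if (s == "train") plan$ratio * n_pos else n_pos

    # Candidate (participant, site) pool over lesion-free participants.
    pool <- list()
    for (id in healthy) {
      m <- lesion_coords
      if (nrow(m))
        pool[[length(pool) + 1L]] <- data.frame(
          participant_id = id, x_mm = m$x_mm, y_mm = m$y_mm, z_mm = m$z_mm,
          provenance = "matched-negative", stringsAsFactors = FALSE)
      b <- cohort$sites[cohort$sites$participant_id == id, , drop = FALSE]
      if (nrow(b))
        pool[[length(pool) + 1L]] <- data.frame(
          participant_id = id, x_mm = b$x_mm, y_mm = b$y_mm, z_mm = b$z_mm,
          provenance = "hard-negative", stringsAsFactors = FALSE)
    }
    pool <- if (length(pool)) do.call(rbind, pool) else
      data.frame(participant_id = character(), x_mm = numeric(),
                 y_mm = numeric(), z_mm = numeric(),
                 provenance = character(), stringsAsFactors = FALSE)
    n_avail <- nrow(pool)
    # a split that drew no lesioned participant still gets a few negatives
    # so that downstream stages (e.g. validation monitoring) stay usable
    if (s != "train" && n_pos == 0L) need <- min(4L, n_avail)
    flips <- all_flips()
    if (need > n_avail * (if (s == "train") n_variant else 1L))
      stop(sprintf(
        "insufficient lesion-free participants in %s split: need %d negatives, can supply %d",
        s, need, n_avail * (if (s == "train") n_variant else 1L)))

    voxels <- matrix(0, PATCH_W^3, n_pos + need)
    meta_id <- character(n_pos + need)
    meta_prov <- character(n_pos + need)
    meta_xyz <- matrix(0, n_pos + need, 3L)

    col <- 0L
    for (id in lesioned) {
      v <- preprocess(cohortVolume(cohort, id), id)
      les <- truth[truth$participant_id == id, , drop = FALSE]
      for (j in seq_len(nrow(les))) {
        ctr <- c(les$x_mm[j], les$y_mm[j], les$z_mm[j])
        if (s == "train") {
          aug <- enumerateAugmentations(v, ctr, label = 1L,
                                        max_offset_mm = plan$max_offset_mm,
                                        n_offsets = plan$n_offsets,
                                        seed = child_seed(plan$seed,
                                                          match(id, manifest$participant_id) * 13L + j))
          for (a in aug) {
            col <- col + 1L
            voxels[, col] <- as.vector(a$voxels)
            meta_id[col] <- id
            meta_prov[col] <- if (all(!a$flip) && all(a$offset_vox == 0L))
              "lesion" else "augmented"
            meta_xyz[col, ] <- a$center_mm
          }
        } else {
          col <- col + 1L
          voxels[, col] <- as.vector(extractPatch(v, ctr))
          meta_id[col] <- id
          meta_prov[col] <- "lesion"
          meta_xyz[col, ] <- ctr
        }
      }
    }
    stopifnot(col == n_pos)

    if (need > 0L) {
      ord <- with_seed(child_seed(plan$seed, match(s, c("train", "val", "test"))),
                       sample.int(n_avail))
      rows <- rep(ord, length.out = need)
      variant <- (seq_len(need) - 1L) %/% n_avail      # 0 = pristine site
      for (id in unique(pool$participant_id[rows])) {
        v <- preprocess(cohortVolume(cohort, id), id)
        for (q in which(pool$participant_id[rows] == id)) {
          site <- pool[rows[q], ]
          flip <- flips[variant[q] %% 8L + 1L, ]
          off <- c(0L, 0L, 0L)
          if (variant[q] %/% 8L > 0L) {
            kmax <- as.integer(floor(plan$max_offset_mm / 0.5))
            off <- with_seed(child_seed(plan$seed, 1000L + q),
                             as.integer(sample(seq(-kmax, kmax), 3L,
                                               replace = TRUE)))
          }
          ctr <- c(site$x_mm, site$y_mm, site$z_mm) + off * voxelSpacing(v)
          idx <- drop(worldToVoxel(v, ctr))
          idx <- pmin(pmax(idx, 1), dim(v))    # keep recycled sites in-bounds
          ctr <- drop(voxelToWorld(v, idx))
          cc <- n_pos + q
          voxels[, cc] <- as.vector(flip_patch(extractPatch(v, ctr), flip))
          meta_id[cc] <- id
          meta_prov[cc] <- if (variant[q] == 0L) site$provenance else
            "augmented"
          meta_xyz[cc, ] <- ctr
        }
      }
    }

    meta <- data.frame(participant_id = meta_id, provenance = meta_prov,
                       x_mm = meta_xyz[, 1], y_mm = meta_xyz[, 2],
                       z_mm = meta_xyz[, 3], stringsAsFactors = FALSE)
    out[[s]] <- new_patch_set(voxels,
                              c(rep(1L, n_pos), rep(0L, need)), meta)
  }
  out
}

#' Write a patch-set manifest as TSV
#'
#' @param sets named list of [PatchSet-class] objects as returned by
#'   [buildTrainingSet()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePatchManifest <- function(sets, path) {
  rows <- lapply(names(sets), function(s) {
    m <- patchMeta(sets[[s]])
    if (!nrow(m)) return(NULL)
    cbind(split = s, label = patchLabels(sets[[s]]), m)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
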