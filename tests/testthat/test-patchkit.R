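test_that("patch extraction is centred, 16 mm wide, and zero-padded", {
  withr::with_seed(2, {
    arr <- array(rnorm(64^3), c(64, 64, 64))
  })
  v <- IntensityVolume(arr, origin = c(0, 0, 0))
  ctr <- drop(voxelToWorld(v, c(30, 31, 32)))
  p <- extractPatch(v, ctr)
  expect_identical(dim(p), c(32L, 32L, 32L))
  # centre voxel of the patch equals the volume value at the centre voxel
  expect_identical(p[17, 17, 17], arr[30, 31, 32])
  expect_identical(p, arr[14:45, 15:46, 16:47])
  # physical extent is 32 voxels * 0.5 mm = 16 mm per axis
  expect_equal(dim(p) * voxelSpacing(v), c(16, 16, 16))

  # a centre 2 voxels from the face zero-fills the out-of-volume margin
  near <- drop(voxelToWorld(v, c(3, 30, 30)))
  q <- extractPatch(v, near)
  expect_true(all(q[1:14, , ] == 0))
  expect_identical(q[15:32, , ], arr[1:18, 14:45, 14:45])
  expect_error(extractPatch(v, c(-10, 0, 0)), "outside")
})

test_that("augmentation enumerates flips and offsets deterministically", {
  v <- IntensityVolume(array(rnorm(48^3), c(48, 48, 48)), origin = c(0, 0, 0))
  ctr <- drop(voxelToWorld(v, c(24, 24, 24)))
  aug0 <- enumerateAugmentations(v, ctr, label = 1L, n_offsets = 0)
  expect_length(aug0, 8L)
  # identity member comes first
  expect_true(all(!aug0[[1]]$flip) && all(aug0[[1]]$offset_vox == 0))
  expect_identical(aug0[[1]]$voxels, extractPatch(v, ctr))
  # flipping twice on one axis returns the original
  f <- VesselVote:::flip_patch
  expect_identical(f(f(aug0[[1]]$voxels, c(TRUE, FALSE, FALSE)),
                     c(TRUE, FALSE, FALSE)), aug0[[1]]$voxels)

  aug <- enumerateAugmentations(v, ctr, label = 1L, max_offset_mm = 4,
                                n_offsets = 3, seed = 11)
  expect_length(aug, 8L * 4L)
  offs <- unique(do.call(rbind, lapply(aug, `[[`, "offset_vox")))
  expect_true(all(abs(offs) <= 8))       # 4 mm at 0.5 mm spacing
  expect_true(all(vapply(aug, `[[`, 0L, "label") == 1L))
  aug2 <- enumerateAugmentations(v, ctr, label = 1L, max_offset_mm = 4,
                                 n_offsets = 3, seed = 11)
  expect_identical(lapply(aug, `[[`, "voxels"), lapply(aug2, `[[`, "voxels"))
})

test_that("participant splits are 80/5/15 with largest-remainder rounding", {
  ids <- sprintf("P%03d", 1:100)
  s <- splitParticipants(ids, seed = 4)
  expect_equal(as.integer(table(s$split)[c("train", "val", "test")]),
               c(80L, 5L, 15L))
  s2 <- splitParticipants(ids, seed = 4)
  expect_identical(s, s2)
  expect_setequal(s$participant_id, ids)
  expect_false(any(duplicated(s$participant_id)))
  expect_error(splitParticipants(c("a", "b"), seed = 1), "at least 3")
  expect_error(splitParticipants(c("a", "a", "b", "c")), "unique")
})

test_that("training sets honour the class ratio, 1:1 eval and no leakage", {
  ch <- mini_cohort(n = 14, prevalence = 0.5, seed = 8)
  # stratified hand-made split: one lesioned + one healthy participant in
  # val and in test, the rest in train
  les_ids <- ch$manifest$participant_id[ch$manifest$label]
  hea_ids <- ch$manifest$participant_id[!ch$manifest$label]
  split <- rbind(
    data.frame(participant_id = c(les_ids[1], hea_ids[1]), split = "val"),
    data.frame(participant_id = c(les_ids[2], hea_ids[2]), split = "test"),
    data.frame(participant_id = setdiff(ch$manifest$participant_id,
                                        c(les_ids[1:2], hea_ids[1:2])),
               split = "train"))
  plan <- samplingPlan("stenosis", n_offsets = 1, seed = 3)
  sets <- buildTrainingSet(ch, plan, split)

  n_pos_train <- sum(patchLabels(sets$train) == 1)
  n_neg_train <- sum(patchLabels(sets$train) == 0)
  expect_equal(n_neg_train, 5L * n_pos_train)
  # train positives expanded 8 * (1 + n_offsets) per lesion
  n_lesions_train <- sum(ch$truth$participant_id %in%
                           split$participant_id[split$split == "train"])
  expect_equal(n_pos_train, 16L * n_lesions_train)

  for (s in c("val", "test")) {
    lab <- patchLabels(sets[[s]])
    if (any(lab == 1)) expect_equal(sum(lab == 0), sum(lab == 1))
  }

  # participant-level leakage: pairwise-disjoint contributor sets
  who <- lapply(sets, function(x) unique(patchMeta(x)$participant_id))
  expect_length(intersect(who$train, who$val), 0L)
  expect_length(intersect(who$train, who$test), 0L)
  expect_length(intersect(who$val, who$test), 0L)

  # provenance covers matched and hard negatives
  prov <- patchMeta(sets$train)$provenance
  expect_true(all(prov %in% c("lesion", "augmented", "matched-negative",
                              "hard-negative")))
  expect_true(any(prov == "matched-negative"))

  # labels are preserved under augmentation
  expect_true(all(patchLabels(sets$train)[prov == "lesion"] == 1L))
})

test_that("an unreachable ratio reports the shortfall", {
  ch <- mini_cohort(n = 6, prevalence = 0.5, seed = 10)
  les_ids <- ch$manifest$participant_id[ch$manifest$label]
  hea_ids <- ch$manifest$participant_id[!ch$manifest$label]
  split <- rbind(
    data.frame(participant_id = c(les_ids[1], hea_ids[1]), split = "val"),
    data.frame(participant_id = setdiff(ch$manifest$participant_id,
                                        c(les_ids[1], hea_ids[1])),
               split = "train"))
  plan <- samplingPlan("stenosis", ratio = 500, n_offsets = 0, seed = 1)
  expect_error(buildTrainingSet(ch, plan, split), "insufficient")
})
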