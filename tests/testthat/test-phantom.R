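test_that("vessel trees are deterministic in the seed and sensitive to it", {
  t1 <- generateVesselTree(1, 2)
  t2 <- generateVesselTree(1, 2)
  t3 <- generateVesselTree(2, 2)
  expect_identical(t1@segments, t2@segments)
  expect_identical(t1@bifurcations, t2@bifurcations)
  expect_false(isTRUE(all.equal(t1@segments[[1]]$points,
                                t3@segments[[1]]$points)))
})

test_that("tree geometry invariants hold across many seeds", {
  box <- roiBox()
  for (seed in 1:100) {
    tree <- generateVesselTree(seed, complexity = 1 + seed %% 3)
    radii <- vapply(tree@segments, `[[`, 1, "radius")
    expect_true(all(radii >= 1 & radii <= 3))
    pts <- do.call(rbind, lapply(tree@segments, `[[`, "points"))
    expect_true(all(t(pts) >= box$lower - 1e-9))
    expect_true(all(t(pts) <= box$upper + 1e-9))
  }
})

test_that("bifurcations are exactly the points shared by >= 3 segment endpoints", {
  tree <- generateVesselTree(7, 2)
  endpoints <- do.call(rbind, lapply(tree@segments, function(s)
    s$points[c(1, nrow(s$points)), , drop = FALSE]))
  shared <- apply(tree@bifurcations, 1, function(b) {
    sum(sqrt(colSums((t(endpoints) - b)^2)) <= 0.25)
  })
  expect_true(all(shared >= 3))
  # complexity 2 -> 2*2 branches and as many bifurcations, 8 segments total
  expect_equal(nrow(tree@bifurcations), 4L)
  expect_length(tree@segments, 8L)
})

test_that("noise-free lesion-free phantom partitions into two intensity values", {
  ph <- rasterizePhantom(generateVesselTree(3), noise_sd = 0, seed = 1)
  vals <- sort(unique(as.vector(volData(ph$volume))))
  expect_length(vals, 2L)
  expect_gte(vals[2] / vals[1], 4)       # vessel at least 4x tissue
  expect_identical(volData(ph$volume) == vals[2],
                   volData(truthMask(ph$truth)))
  expect_false(participantLabel(ph$truth))
})

test_that("phantom volumes are bitwise reproducible for a fixed seed", {
  tree <- generateVesselTree(4)
  a <- rasterizePhantom(tree, noise_sd = 0.1, seed = 9)
  b <- rasterizePhantom(tree, noise_sd = 0.1, seed = 9)
  expect_identical(volData(a$volume), volData(b$volume))
})

test_that("a 50% stenosis on a radius-2mm arc halves the local radius", {
  tree <- generateVesselTree(11)
  # pick a ring arc (first segments) and scale it to exactly 2 mm
  tree@segments[[1]]$radius <- 2.0
  pts <- tree@segments[[1]]$points
  ctr <- pts[ceiling(nrow(pts) / 2), ]
  les <- lesionSpec("stenosis", ctr, severity = 0.5, extent_mm = 6)
  ph <- rasterizePhantom(tree, les, noise_sd = 0, seed = 1)
  mask <- volData(truthMask(ph$truth))
  # maximal distance from the lesion centre point to mask voxels within a
  # thin slab around it estimates the local radius
  vol <- ph$volume
  idx <- which(mask, arr.ind = TRUE)
  mm <- voxelToWorld(vol, idx)
  d <- sqrt(colSums((t(mm) - ctr)^2))
  near <- d < 2.5                       # voxels in the stenotic throat
  expect_gt(sum(near), 0)
  # radius of the in-slab cross-section: max perpendicular distance of
  # retained voxels from the centreline point, should be ~1 mm (not ~2)
  r_local <- max(apply(mm[near, , drop = FALSE], 1, function(p) {
    sqrt(sum((p - ctr)^2))
  }))
  expect_lt(r_local, 2.5 * 1.0 + 0.01)  # well below nominal 2 mm tube extent
  # and the throat is genuinely narrower than the untouched vessel:
  ph0 <- rasterizePhantom(tree, noise_sd = 0, seed = 1)
  expect_lt(sum(volData(truthMask(ph$truth))),
            sum(volData(truthMask(ph0$truth))))
})

test_that("stenosis severity monotonically shrinks the local cross-section", {
  tree <- generateVesselTree(12)
  pts <- tree@segments[[2]]$points
  ctr <- pts[ceiling(nrow(pts) / 2), ]
  counts <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(sev) {
    les <- lesionSpec("stenosis", ctr, severity = sev, extent_mm = 6)
    ph <- rasterizePhantom(tree, les, noise_sd = 0, seed = 1)
    sum(volData(truthMask(ph$truth)))
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("occlusions void the flow signal over their extent without narrowing", {
  tree <- generateVesselTree(13)
  pts <- tree@segments[[1]]$points
  ctr <- pts[ceiling(nrow(pts) / 2), ]
  les <- lesionSpec("occlusion", ctr, extent_mm = 8)
  ph <- rasterizePhantom(tree, les, noise_sd = 0, seed = 1)
  v <- volData(ph$volume)
  mask <- volData(truthMask(ph$truth))
  # mask voxels at the occlusion read tissue intensity
  idx <- which(mask, arr.ind = TRUE)
  mm <- voxelToWorld(ph$volume, idx)
  d <- sqrt(colSums((t(mm) - ctr)^2))
  occl_vox <- idx[d < 3, , drop = FALSE]
  expect_gt(nrow(occl_vox), 0)
  expect_true(all(v[occl_vox] == min(v)))
  # geometry untouched: occluded phantom mask equals lesion-free mask
  ph0 <- rasterizePhantom(tree, noise_sd = 0, seed = 1)
  expect_identical(mask, volData(truthMask(ph0$truth)))
})

test_that("aneurysms add a bright sac tangent to the wall", {
  tree <- generateVesselTree(14)
  pts <- tree@segments[[1]]$points
  ctr <- pts[ceiling(nrow(pts) / 2), ]
  les <- lesionSpec("aneurysm", ctr, size_mm = 4)
  ph <- rasterizePhantom(tree, les, noise_sd = 0, seed = 1)
  sac <- ph$truth@aneurysmMask
  expect_gt(sum(sac), 0)
  expect_true(all(volData(ph$volume)[sac] == max(volData(ph$volume))))
  # sac voxel count approximates a sphere of diameter 4 mm
  expect_equal(sum(sac) * 0.5^3, 4 / 3 * pi * 2^3, tolerance = 0.25)
})

test_that("lesion specs enforce the case definitions", {
  expect_error(lesionSpec("stenosis", c(0, 0, 0), severity = 0.4,
                          extent_mm = 5), "0.5")
  expect_error(lesionSpec("stenosis", c(0, 0, 0), severity = 1,
                          extent_mm = 5), "0.5")
  expect_error(lesionSpec("occlusion", c(0, 0, 0), severity = 0.7,
                          extent_mm = 5), "exactly 1")
  expect_error(lesionSpec("aneurysm", c(0, 0, 0), size_mm = 1.5), "2 mm")
  expect_error(rasterizePhantom(
    generateVesselTree(1),
    lesionSpec("stenosis", c(50, 39, 5), severity = 0.6, extent_mm = 5),
    noise_sd = 0, seed = 1), "lesion 1 \\(stenosis\\)")
})

test_that("cohort prevalence uses round-half-up and honours the lesion mix", {
  ch <- makeCohort(100, 0.066, c(stenosis = 1), noise_sd = 0, seed = 2,
                   out_dir = NULL, render = FALSE)
  expect_equal(sum(ch$manifest$label), 7L)
  expect_true(all(ch$truth$kind == "stenosis"))
  expect_gte(nrow(ch$truth), 7L)        # affected members carry >= 1 lesion
  ch0 <- makeCohort(10, 0, c(stenosis = 1), noise_sd = 0, seed = 2,
                    render = FALSE)
  expect_equal(sum(ch0$manifest$label), 0L)
  expect_equal(nrow(ch0$truth), 0L)
  expect_error(makeCohort(0, 0.5), "positive")
  expect_error(makeCohort(10, 0.5, c(stenosis = 0.5)), "sum to 1")
})

test_that("cohorts written to disk are reproducible and readable back", {
  d1 <- file.path(tempdir(), "coh_a")
  d2 <- file.path(tempdir(), "coh_b")
  unlink(c(d1, d2), recursive = TRUE)
  makeCohort(2, 0.5, c(stenosis = 1), noise_sd = 0.1, seed = 3, out_dir = d1)
  makeCohort(2, 0.5, c(stenosis = 1), noise_sd = 0.1, seed = 3, out_dir = d2)
  ch <- readCohort(d1)
  expect_equal(nrow(ch$manifest), 2L)
  v1 <- cohortVolume(ch, "P001")
  v2 <- cohortVolume(readCohort(d2), "P001")
  expect_identical(volData(v1), volData(v2))
  expect_true(all(c("x_mm", "y_mm", "z_mm") %in% colnames(ch$sites)))
})
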