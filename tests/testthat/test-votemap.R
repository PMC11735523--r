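# A deterministic stand-in classifier for lattice tests: probability is a
# smooth function of the mean window intensity.
fn_model <- function(X) plogis(10 * (colMeans(X) - 0.1))

test_that("lattice dimensions follow the floor convention", {
  expect_identical(latticeDims(c(204L, 146L, 156L), 4L),
                   c(44L, 29L, 32L))
  expect_equal(prod(latticeDims(c(204L, 146L, 156L), 4L)), 40832)
  expect_identical(latticeDims(c(32L, 32L, 32L), 4L), c(1L, 1L, 1L))
  expect_identical(latticeDims(c(35L, 36L, 39L), 4L), c(1L, 2L, 2L))
})

test_that("sliding inference fills the lattice and respects the mask toggle", {
  withr::with_seed(5, {
    arr <- array(runif(48 * 44 * 40), c(48, 44, 40))
  })
  v <- IntensityVolume(arr, origin = c(0, 0, 0))
  lat <- slideInfer(function(X) rep(1, ncol(X)), v, stride = 4)
  expect_identical(dim(latticeValues(lat)), latticeDims(dim(v), 4L))
  expect_true(all(latticeValues(lat) == 1))

  one <- slideInfer(fn_model, IntensityVolume(arr[1:32, 1:32, 1:32]),
                    stride = 4)
  expect_identical(dim(latticeValues(one)), c(1L, 1L, 1L))

  expect_error(slideInfer(fn_model, IntensityVolume(arr[1:16, , ])),
               "window")

  # windows with no mask voxel are skipped (probability 0)
  m <- array(FALSE, c(48, 44, 40))
  m[40:48, 36:44, 32:40] <- TRUE       # only the far corner is vessel
  masked <- slideInfer(function(X) rep(1, ncol(X)), v,
                       mask = VesselMask(m, origin = c(0, 0, 0)), stride = 4)
  mv <- latticeValues(masked)
  expect_true(mv[dim(mv)[1], dim(mv)[2], dim(mv)[3]] == 1)
  expect_true(mv[1, 1, 1] == 0)
  # exactly the windows overlapping the mask corner are scored
  ld <- dim(mv)
  scored <- which(mv == 1, arr.ind = TRUE)
  starts <- (scored - 1L) * 4L + 1L
  overlaps <- starts + 31L >= rep(c(40L, 36L, 32L), each = nrow(starts))
  expect_true(all(overlaps))
})

test_that("inference through a trained classifier is deterministic", {
  clf <- trainClassifier(buildModel(modelConfig("small-3d", seed = 2)),
                         toy_patch_set(6, 6, seed = 10),
                         toy_patch_set(2, 2, seed = 11),
                         trainConfig(max_epochs = 1, patience = 0,
                                     batch_size = 4, seed = 1))
  v <- IntensityVolume(array(rnorm(36^3), c(36, 36, 36)))
  a <- slideInfer(clf, v, stride = 4)
  b <- slideInfer(clf, v, stride = 4)
  expect_identical(latticeValues(a), latticeValues(b))
  expect_true(all(latticeValues(a) >= 0 & latticeValues(a) <= 1))
})

test_that("thresholding at the operating point separates probabilities", {
  lat <- new("ProbabilityLattice",
             values = array(c(0.9996, 0.9990, 0.5, 1), c(4, 1, 1)),
             stride = 4L, window = 32L, spacing = rep(0.5, 3),
             origin = c(0, 0, 0), roiDim = c(44L, 32L, 32L))
  b <- thresholdLattice(lat, 0.99954)
  expect_identical(as.vector(latticeValues(b)), c(1, 0, 0, 1))
  expect_true(all(latticeValues(thresholdLattice(lat, 0)) == 1))
  # raising tau never increases the positive count
  taus <- c(0, 0.5, 0.999, 0.99954, 1)
  pos <- vapply(taus, function(t) sum(latticeValues(thresholdLattice(lat, t))), 0)
  expect_true(all(diff(pos) <= 0))
})

test_that("findings need 25 adjacent positives and match the flood-fill oracle", {
  mk <- function(values, ld) {
    new("ProbabilityLattice", values = array(values, ld), stride = 4L,
        window = 32L, spacing = rep(0.5, 3), origin = c(0, 0, 0),
        roiDim = as.integer(ld * 4L + 28L))
  }
  # one 5x5x1 block: exactly 25 adjacent positives -> one finding
  v <- array(0, c(10, 10, 5)); v[2:6, 2:6, 2] <- 1
  f <- extractFindings(mk(v, c(10, 10, 5)), min_support = 25)
  expect_equal(nrow(f), 1L)
  expect_equal(f$component_size, 25L)
  # removing one voxel (24) -> none
  v24 <- v; v24[2, 2, 2] <- 0
  expect_equal(nrow(extractFindings(mk(v24, c(10, 10, 5)),
                                    min_support = 25)), 0L)

  # random lattices against the oracle, all connectivities
  withr::with_seed(31, {
    for (rep in 1:5) {
      for (conn in c(6L, 18L, 26L)) {
        r <- array(runif(9 * 8 * 7) > 0.5, c(9, 8, 7))
        lab <- oracle_flood_fill(r, conn)
        ff <- extractFindings(mk(r * 1, dim(r)), min_support = 1,
                              connectivity = conn)
        expect_identical(sort(ff$component_size),
                         as.integer(component_sizes(lab)))
      }
    }
  })
})

test_that("finding centroids map to world space inside the ROI", {
  v <- array(0, c(44, 29, 32)); v[10:14, 10:14, 10] <- 1
  lat <- new("ProbabilityLattice", values = v, stride = 4L, window = 32L,
             spacing = rep(0.5, 3),
             origin = drop(voxelToWorld(IntensityVolume(array(0, roiDim())),
                                        c(17, 17, 17))),
             roiDim = roiDim())
  f <- extractFindings(lat, min_support = 25)
  expect_equal(nrow(f), 1L)
  ctr <- c(f$x_mm, f$y_mm, f$z_mm)
  expect_true(all(ctr >= roiBox()$lower & ctr <= roiBox()$upper))
  # centroid of lattice indices (12,12,10) -> origin + (idx-1)*stride*0.5
  expect_equal(ctr, lat@origin + (c(12, 12, 10) - 1) * 2)
})

test_that("the findings count is monotone in support and the decision in findings", {
  withr::with_seed(8, {
    v <- array(runif(12^3) > 0.4, c(12, 12, 12)) * 1
  })
  lat <- new("ProbabilityLattice", values = v, stride = 4L, window = 32L,
             spacing = rep(0.5, 3), origin = c(0, 0, 0),
             roiDim = c(12L, 12L, 12L) * 4L + 28L)
  ns <- vapply(c(1, 5, 10, 25, 50),
               function(k) nrow(extractFindings(lat, min_support = k)), 0)
  expect_true(all(diff(ns) <= 0))
  expect_false(participantDecision(extractFindings(lat, min_support = 1e6)))
  f <- extractFindings(lat, min_support = 1)
  expect_identical(participantDecision(f), nrow(f) > 0)
  expect_identical(participantDecision(f[rev(seq_len(nrow(f))), ]),
                   participantDecision(f))
})
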