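test_that("confusion counts align participants and sum to cohort size", {
  pred <- c(a = TRUE, b = FALSE, c = TRUE, d = FALSE)
  truth <- c(d = FALSE, c = TRUE, b = TRUE, a = TRUE)
  cc <- confusionCounts(pred, truth)
  expect_equal(c(cc@tp, cc@fp, cc@tn, cc@fn), c(2L, 0L, 1L, 1L))
  expect_equal(confusionTotal(cc), 4L)
  expect_error(confusionCounts(pred, truth[1:3]), "different participants")
  expect_error(confusionCounts(c(a = TRUE), c(x = TRUE)),
               "different participants")

  perfect <- confusionCounts(rep(c(TRUE, FALSE), c(6, 4)),
                             rep(c(TRUE, FALSE), c(6, 4)))
  expect_equal(c(perfect@tp, perfect@tn, perfect@fp, perfect@fn),
               c(6L, 4L, 0L, 0L))
  allneg <- confusionCounts(rep(FALSE, 34), rep(c(TRUE, FALSE), each = 17))
  expect_equal(c(allneg@fn, allneg@tn), c(17L, 17L))
})

test_that("diagnostic fractions reproduce the published two-by-two tables", {
  # balanced test set of 34, aneurysm arm: 13/4/4/13
  r1 <- diagnosticMetrics(ConfusionCounts(tp = 13, fn = 4, fp = 4, tn = 13))
  expect_equal(round(100 * r1@accuracy, 1), 76.5)
  expect_equal(r1@accuracy, 26 / 34)
  expect_equal(r1@sensitivity, 13 / 17)
  expect_equal(r1@specificity, 13 / 17)
  expect_equal(r1@ppv, 13 / 17)

  # stenosis arm: 13/4/2/15
  r2 <- diagnosticMetrics(ConfusionCounts(tp = 13, fn = 4, fp = 2, tn = 15))
  expect_equal(round(100 * r2@accuracy, 1), 82.4)
  expect_equal(r2@accuracy, 28 / 34)
  expect_equal(round(100 * r2@ppv, 1), 86.7)
  expect_equal(r2@ppv, 13 / 15)
  expect_equal(round(100 * r2@specificity, 1), 88.2)
  expect_equal(r2@specificity, 15 / 17)
})

test_that("zero denominators are flagged undefined, never silently 0", {
  r <- diagnosticMetrics(ConfusionCounts(tp = 0, fn = 0, fp = 3, tn = 7))
  expect_true(is.na(r@sensitivity))
  expect_true("sensitivity" %in% r@undefined)
  expect_false(identical(r@sensitivity, 0))
  expect_error(diagnosticMetrics(ConfusionCounts(0, 0, 0, 0)), "zero")
})

test_that("prevalence adjustment follows Bayes' rule and its limits", {
  adj <- prevalenceAdjusted(1, 1, 0.3)
  expect_equal(unname(adj), c(1, 1))
  adj2 <- prevalenceAdjusted(0.5, 0.5, 0.5)
  expect_equal(unname(adj2), c(0.5, 0.5))
  # for a balanced cohort the adjusted values at p = 0.5 equal raw PPV/NPV
  cc <- ConfusionCounts(tp = 13, fn = 4, fp = 2, tn = 15)
  r <- diagnosticMetrics(cc)
  adj3 <- prevalenceAdjusted(r@sensitivity, r@specificity, 0.5)
  expect_equal(unname(adj3[["prev_ppv"]]), r@ppv)
  expect_equal(unname(adj3[["prev_npv"]]), r@npv)
  # monotonicity in prevalence on a grid
  ps <- seq(0.01, 0.99, by = 0.07)
  vals <- t(vapply(ps, function(p) prevalenceAdjusted(0.8, 0.9, p),
                   c(prev_ppv = 0, prev_npv = 0)))
  expect_true(all(diff(vals[, "prev_ppv"]) >= 0))
  expect_true(all(diff(vals[, "prev_npv"]) <= 0))
  expect_error(prevalenceAdjusted(1.2, 0.5, 0.5))
})

test_that("stratified sensitivities are per-lesion fractions with flags", {
  det <- c(rep(TRUE, 8), FALSE, TRUE, FALSE, FALSE)
  str <- c(rep("ICA", 9), rep("occlusion", 3))
  s <- stratifiedSensitivity(det, str)
  expect_equal(s$sensitivity[s$stratum == "ICA"], 8 / 9)
  expect_equal(round(100 * s$sensitivity[s$stratum == "ICA"], 1), 88.9)
  expect_equal(s$sensitivity[s$stratum == "occlusion"], 1 / 3)
  expect_equal(round(100 * s$sensitivity[s$stratum == "occlusion"], 1), 33.3)
  # merged moderate+severe stratum: 12 of 14
  s2 <- stratifiedSensitivity(rep(c(TRUE, FALSE), c(12, 2)),
                              rep("moderate+severe", 14))
  expect_equal(round(100 * s2$sensitivity, 1), 85.7)
  expect_error(stratifiedSensitivity(c(TRUE, FALSE), "a"), "one stratum")
  r <- diagnosticMetrics(ConfusionCounts(1, 1, 1, 1),
                         strata = stratifiedSensitivity(logical(0),
                                                        character(0)))
  expect_length(r@strata, 0L)
})

test_that("greedy one-to-one matching pairs findings with lesions", {
  lesions <- data.frame(x_mm = c(0, 20), y_mm = c(0, 0), z_mm = c(0, 0))
  hit <- data.frame(component_size = 30L, x_mm = 0, y_mm = 0, z_mm = 0)
  m <- matchFindingsToTruth(hit, lesions, tol_mm = 8)
  expect_identical(m$detected, c(TRUE, FALSE))
  expect_length(m$false_positives, 0L)

  none <- matchFindingsToTruth(hit[0, ], lesions, tol_mm = 8)
  expect_identical(none$detected, c(FALSE, FALSE))

  # two findings near one lesion: one hit, one false positive
  two <- data.frame(component_size = c(30L, 28L), x_mm = c(1, -1),
                    y_mm = c(0, 0), z_mm = c(0, 0))
  m2 <- matchFindingsToTruth(two, lesions[1, , drop = FALSE], tol_mm = 8)
  expect_equal(sum(m2$detected), 1L)
  expect_length(m2$false_positives, 1L)
  # beyond tolerance nothing matches
  far <- data.frame(component_size = 30L, x_mm = 50, y_mm = 0, z_mm = 0)
  expect_false(any(matchFindingsToTruth(far, lesions, 8)$detected))
})

test_that("reports serialise to JSON with bare numbers", {
  r <- diagnosticMetrics(ConfusionCounts(13, 2, 15, 4),
                         prevalence = 0.06)
  f <- tempfile(fileext = ".json")
  writeReport(r, f, counts = ConfusionCounts(13, 2, 15, 4))
  j <- jsonlite::read_json(f)
  expect_equal(j$accuracy, 28 / 34, tolerance = 1e-12)
  expect_equal(j$confusion$tp, 13L)
  expect_false(is.list(j$accuracy))
})
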