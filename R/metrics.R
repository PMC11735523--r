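# Participant-level evaluation: confusion counts, the standard diagnostic
# fractions, per-stratum sensitivities, prevalence-adjusted predictive
# values, and matching of voting findings to ground-truth lesions.

#' Construct confusion counts
#'
#' Either give the four counts directly, or derive them from per-participant
#' predictions and truth with [confusionCounts()].
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return A [ConfusionCounts-class].
#' @export
ConfusionCounts <- function(tp, fp, tn, fn) {
  new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn))
}

#' Confusion counts from participant-level predictions
#'
#' @param predicted,truth logical vectors over the same participants.  When
#'   both are named the vectors are aligned by name, and differing
#'   participant sets are an error.
#' @return A [ConfusionCounts-class].
#' @examples
#' confusionCounts(c(TRUE, FALSE, TRUE), c(TRUE, TRUE, FALSE))
#' @export
confusionCounts <- function(predicted, truth) {
  if (!is.null(names(predicted)) && !is.null(names(truth))) {
    if (!setequal(names(predicted), names(truth)))
      stop("predicted and truth cover different participants")
    truth <- truth[names(predicted)]
  } else if (length(predicted) != length(truth)) {
    stop("predicted and truth cover different participants")
  }
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  ConfusionCounts(tp = sum(predicted & truth),
                  fp = sum(predicted & !truth),
                  tn = sum(!predicted & !truth),
                  fn = sum(!predicted & truth))
}

#' @describeIn confusionCounts total number of participants.
#' @param counts a [ConfusionCounts-class].
#' @export
confusionTotal <- function(counts) {
  counts@tp + counts@fp + counts@tn + counts@fn
}

setMethod("show", "ConfusionCounts", function(object) {
  m <- matrix(c(object@tp, object@fp, object@fn, object@tn), 2, 2,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  cat("ConfusionCounts (participants)\n")
  print(m)
})

safe_frac <- function(num, den) if (den == 0) NA_real_ else num / den

#' Diagnostic metrics from confusion counts
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/total`, PPV `tp/(tp+fp)` and NPV `tn/(tn+fn)`.  Metrics with a
#' zero denominator are returned as `NA` and listed in the report's
#' `undefined` slot -- never silently 0.  Optionally attaches per-stratum
#' sensitivities (see [stratifiedSensitivity()]) and prevalence-adjusted
#' predictive values (see [prevalenceAdjusted()]).
#'
#' @param counts a [ConfusionCounts-class] with a positive total.
#' @param strata optional data.frame from [stratifiedSensitivity()].
#' @param prevalence optional population prevalence for adjusted predictive
#'   values.
#' @return A [DiagnosticReport-class].
#' @examples
#' r <- diagnosticMetrics(ConfusionCounts(tp = 13, fn = 4, fp = 2, tn = 15))
#' r@accuracy                         # 28/34
#' @export
diagnosticMetrics <- function(counts, strata = NULL, prevalence = NULL) {
  validObject(counts)
  total <- confusionTotal(counts)
  if (total == 0L) stop("confusion counts sum to zero")
  vals <- c(sensitivity = safe_frac(counts@tp, counts@tp + counts@fn),
            specificity = safe_frac(counts@tn, counts@tn + counts@fp),
            accuracy = safe_frac(counts@tp + counts@tn, total),
            ppv = safe_frac(counts@tp, counts@tp + counts@fp),
            npv = safe_frac(counts@tn, counts@tn + counts@fn))
  undefined <- names(vals)[is.na(vals)]
  prevPPV <- NA_real_; prevNPV <- NA_real_; prev <- NA_real_
  if (!is.null(prevalence)) {
    prev <- prevalence
    adj <- prevalenceAdjusted(vals["sensitivity"], vals["specificity"],
                              prevalence)
    prevPPV <- adj[["prev_ppv"]]
    prevNPV <- adj[["prev_npv"]]
    undefined <- c(undefined,
                   c("prev_ppv", "prev_npv")[is.na(c(prevPPV, prevNPV))])
  }
  sv <- numeric(0)
  sc <- data.frame()
  if (!is.null(strata)) {
    sv <- stats::setNames(strata$sensitivity, strata$stratum)
    sc <- strata
    undefined <- c(undefined,
                   paste0("stratum:",
                          strata$stratum[is.na(strata$sensitivity)],
                          recycle0 = TRUE))
  }
  new("DiagnosticReport", sensitivity = unname(vals["sensitivity"]),
      specificity = unname(vals["specificity"]),
      accuracy = unname(vals["accuracy"]), ppv = unname(vals["ppv"]),
      npv = unname(vals["npv"]), strata = sv, strataCounts = sc,
      prevalence = prev, prevPPV = prevPPV, prevNPV = prevNPV,
      undefined = undefined)
}

fmt_pct <- function(x) if (is.na(x)) "undefined" else sprintf("%.1f%%", 100 * x)

setMethod("show", "DiagnosticReport", function(object) {
  cat("DiagnosticReport (participant level)\n")
  cat(sprintf("  accuracy     %s\n", fmt_pct(object@accuracy)))
  cat(sprintf("  sensitivity  %s\n", fmt_pct(object@sensitivity)))
  cat(sprintf("  specificity  %s\n", fmt_pct(object@specificity)))
  cat(sprintf("  PPV          %s\n", fmt_pct(object@ppv)))
  cat(sprintf("  NPV          %s\n", fmt_pct(object@npv)))
  if (!is.na(object@prevalence)) {
    cat(sprintf("  at prevalence %.1f%%: PPV %s, NPV %s\n",
                100 * object@prevalence, fmt_pct(object@prevPPV),
                fmt_pct(object@prevNPV)))
  }
  if (length(object@strata)) {
    cat("  sensitivity by stratum:\n")
    for (s in names(object@strata))
      cat(sprintf("    %-18s %s\n", s, fmt_pct(object@strata[[s]])))
  }
  if (length(object@undefined))
    cat("  undefined:", paste(object@undefined, collapse = ", "), "\n")
})

#' Prevalence-adjusted predictive values
#'
#' Rescales predictive values from a balanced test set to a population
#' prevalence by Bayes' rule:
#' `prev_ppv = s * p / (s * p + (1 - c) * (1 - p))` and
#' `prev_npv = c * (1 - p) / ((1 - s) * p + c * (1 - p))`
#' for sensitivity `s`, specificity `c` and prevalence `p`.
#'
#' @param sensitivity,specificity,prevalence fractions in [0, 1].
#' @return Named numeric vector `c(prev_ppv, prev_npv)`; a value whose
#'   denominator is zero is `NA`.
#' @examples
#' prevalenceAdjusted(13 / 17, 15 / 17, 0.06)
#' @export
prevalenceAdjusted <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0,
            specificity <= 1, prevalence >= 0, prevalence <= 1)
  s <- as.numeric(sensitivity); cc <- as.numeric(specificity)
  p <- as.numeric(prevalence)
  den_p <- s * p + (1 - cc) * (1 - p)
  den_n <- (1 - s) * p + cc * (1 - p)
  c(prev_ppv = if (den_p == 0) NA_real_ else s * p / den_p,
    prev_npv = if (den_n == 0) NA_real_ else cc * (1 - p) / den_n)
}

#' Per-stratum sensitivity over lesions
#'
#' Sensitivities are computed over lesions (not participants):
#' `detected / total` within each stratum, e.g. by artery or severity
#' grade.  Strata with no lesions are `NA` (flagged, never 0).
#'
#' @param detected logical vector, one entry per lesion.
#' @param stratum character/factor vector assigning each lesion a stratum.
#' @return data.frame with columns `stratum`, `detected`, `total`,
#'   `sensitivity`.
#' @examples
#' stratifiedSensitivity(c(TRUE, TRUE, FALSE), c("ICA", "ICA", "MCA"))
#' @export
stratifiedSensitivity <- function(detected, stratum) {
  if (length(detected) != length(stratum))
    stop("every lesion needs exactly one stratum")
  stratum <- as.character(stratum)
  levels <- unique(stratum)
  if (!length(levels))
    return(data.frame(stratum = character(), detected = integer(),
                      total = integer(), sensitivity = numeric(),
                      stringsAsFactors = FALSE))
  rows <- lapply(levels, function(s) {
    sel <- stratum == s
    tot <- sum(sel)
    data.frame(stratum = s, detected = sum(detected[sel]), total = tot,
               sensitivity = safe_frac(sum(detected[sel]), tot),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Match findings to ground-truth lesions
#'
#' Greedy nearest-first one-to-one matching: repeatedly pair the globally
#' closest (finding, lesion) couple within `tol_mm`, then remove both.  A
#' lesion is detected iff it receives a finding; findings left unmatched
#' are false positives.  The default tolerance of 8 mm is half a patch
#' edge.
#'
#' @param findings data.frame from [extractFindings()].
#' @param lesions lesion table with columns `x_mm`, `y_mm`, `z_mm`.
#' @param tol_mm positive matching tolerance in mm.
#' @return list with `detected` (logical per lesion), `matched_finding`
#'   (finding row index per lesion, NA if missed), and `false_positives`
#'   (row indices of unmatched findings).
#' @export
matchFindingsToTruth <- function(findings, lesions, tol_mm = 8) {
  stopifnot(tol_mm > 0)
  nf <- nrow(findings); nl <- nrow(lesions)
  detected <- rep(FALSE, nl)
  matched <- rep(NA_integer_, nl)
  if (nf == 0L || nl == 0L)
    return(list(detected = detected, matched_finding = matched,
                false_positives = seq_len(nf)))
  fm <- as.matrix(findings[, c("x_mm", "y_mm", "z_mm")])
  lm <- as.matrix(lesions[, c("x_mm", "y_mm", "z_mm")])
  d <- sqrt(outer(rowSums(fm^2), rowSums(lm^2), "+") - 2 * fm %*% t(lm))
  d[!is.finite(d)] <- Inf
  free_f <- rep(TRUE, nf); free_l <- rep(TRUE, nl)
  repeat {
    dd <- d
    dd[!free_f, ] <- Inf
    dd[, !free_l] <- Inf
    if (all(!is.finite(dd)) || min(dd) > tol_mm) break
    ij <- which(dd == min(dd), arr.ind = TRUE)[1L, ]
    detected[ij[2L]] <- TRUE
    matched[ij[2L]] <- ij[1L]
    free_f[ij[1L]] <- FALSE
    free_l[ij[2L]] <- FALSE
  }
  list(detected = detected, matched_finding = matched,
       false_positives = which(free_f))
}

#' Serialise a diagnostic report as JSON
#'
#' @param report a [DiagnosticReport-class].
#' @param counts optional [ConfusionCounts-class] included verbatim.
#' @param path output path.
#' @param extra named list merged into the JSON object (e.g. config hash).
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, counts = NULL, extra = list()) {
  x <- list(accuracy = report@accuracy, sensitivity = report@sensitivity,
            specificity = report@specificity, ppv = report@ppv,
            npv = report@npv, prevalence = report@prevalence,
            prev_ppv = report@prevPPV, prev_npv = report@prevNPV,
            undefined = report@undefined)
  if (length(report@strata)) x$sensitivity_by_stratum <- as.list(report@strata)
  if (!is.null(counts))
    x$confusion <- list(tp = counts@tp, fp = counts@fp, tn = counts@tn,
                        fn = counts@fn)
  x <- c(x, extra)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}
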