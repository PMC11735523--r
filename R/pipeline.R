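# End-to-end orchestration: simulate -> segment -> patches -> train ->
# detect -> eval, driven by one config and one master seed.

#' Pipeline configuration
#'
#' Collects every stage's configuration with mode-dependent defaults:
#' vessel segmentation is applied in stenosis mode and skipped in aneurysm
#' mode, and the training class ratio is 5:1 for stenosis and 4:1 for
#' aneurysms.  All stage seeds are fixed offsets of the global `seed`.
#'
#' The default cohort sizes (60 training phantoms and 20 held-out
#' evaluation phantoms at prevalence 0.5, noise 0.1) together with
#' `epochs = 10` on the `small-3d` preset define the package's desk-scale
#' phantom experiment.
#'
#' @param mode `"stenosis"` or `"aneurysm"`.
#' @param seed global integer seed.
#' @param out_dir output directory for all artifacts.
#' @param n_train,train_prevalence training cohort size and prevalence.
#' @param n_eval,eval_prevalence held-out evaluation cohort size and
#'   prevalence.
#' @param noise_sd phantom noise level.
#' @param complexity vessel-tree complexity.
#' @param lesion_mix named lesion-kind fractions; defaults to all-stenosis
#'   or all-aneurysm by mode.
#' @param use_segmentation overrides the mode default.
#' @param min_voxels,connectivity small-cluster pruning parameters.
#' @param model_preset `"small-3d"` (default) or `"resnet50-3d"`.
#' @param epochs,learning_rate,batch_size,patience,pos_weight training
#'   parameters; `pos_weight` defaults to the class ratio so positive and
#'   negative patches contribute equally to the loss.
#' @param ratio training negatives per positive; mode default when `NULL`.
#' @param n_offsets,max_offset_mm augmentation policy.
#' @param stride,tau,min_support voting parameters.
#' @param match_tol_mm finding-to-lesion matching tolerance.
#' @param population_prevalence prevalence used for adjusted predictive
#'   values (default 0.06).
#' @return A list of class `pipeline_config`.
#' @export
pipelineConfig <- function(mode = c("stenosis", "aneurysm"), seed = 1L,
                           out_dir = tempfile("vesselvote"),
                           n_train = 60L, train_prevalence = 0.5,
                           n_eval = 20L, eval_prevalence = 0.5,
                           noise_sd = 0.1, complexity = 2L,
                           lesion_mix = NULL, use_segmentation = NULL,
                           min_voxels = 3500L, connectivity = 26L,
                           model_preset = "small-3d", epochs = 10L,
                           learning_rate = 3e-3, batch_size = 32L,
                           patience = NULL, pos_weight = NULL,
                           ratio = NULL, n_offsets = 3L,
                           max_offset_mm = 4, stride = 4L, tau = 0.99954,
                           min_support = 25L, match_tol_mm = 8,
                           population_prevalence = 0.06) {
  mode <- match.arg(mode)
  if (is.null(lesion_mix))
    lesion_mix <- if (mode == "aneurysm") c(aneurysm = 1) else c(stenosis = 1)
  if (is.null(use_segmentation)) use_segmentation <- mode == "stenosis"
  if (is.null(ratio)) ratio <- if (mode == "aneurysm") 4L else 5L
  if (is.null(patience)) patience <- max(0L, as.integer(epochs) - 1L)
  if (is.null(pos_weight)) pos_weight <- as.numeric(ratio)
  cfg <- list(mode = mode, seed = as.integer(seed), out_dir = out_dir,
              n_train = as.integer(n_train),
              train_prevalence = train_prevalence,
              n_eval = as.integer(n_eval),
              eval_prevalence = eval_prevalence, noise_sd = noise_sd,
              complexity = as.integer(complexity), lesion_mix = lesion_mix,
              use_segmentation = use_segmentation,
              min_voxels = as.integer(min_voxels),
              connectivity = as.integer(connectivity),
              model_preset = model_preset, epochs = as.integer(epochs),
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              patience = as.integer(patience),
              pos_weight = as.numeric(pos_weight),
              ratio = as.integer(ratio),
              n_offsets = as.integer(n_offsets),
              max_offset_mm = max_offset_mm, stride = as.integer(stride),
              tau = tau, min_support = as.integer(min_support),
              match_tol_mm = match_tol_mm,
              population_prevalence = population_prevalence)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file with `pipelineConfig()` arguments.
#' @param ... overrides applied on top of the file.
#' @export
readPipelineConfig <- function(path, ...) {
  args <- yaml::read_yaml(path)
  over <- list(...)
  args[names(over)] <- over
  if (!is.null(args$lesion_mix)) args$lesion_mix <- unlist(args$lesion_mix)
  do.call(pipelineConfig, args)
}

pipeline_log <- function(state, stage, fmt, ...) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...))
  if (!isTRUE(state$quiet)) message(line)
  if (!is.null(state$logfile)) cat(line, "\n", file = state$logfile,
                                   append = TRUE)
}

run_stage <- function(state, stage, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  pipeline_log(state, stage, "done in %.1fs",
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
  res
}

# Mask (optionally) and standardise a volume to zero mean / unit variance;
# the identical preprocessing is applied before patch extraction and before
# sliding-window inference.
preprocess_volume <- function(volume, mask = NULL) {
  x <- volData(volume)
  if (!is.null(mask)) x <- x * volData(mask)
  mu <- mean(x)
  sd <- stats::sd(as.vector(x))
  if (sd < 1e-12) sd <- 1
  IntensityVolume((x - mu) / sd, spacing = voxelSpacing(volume),
                  origin = volOrigin(volume))
}

#' Run the full detection pipeline on synthetic phantoms
#'
#' Executes, in order: phantom cohort simulation, vessel segmentation
#' (stenosis mode), participant-level 80/5/15 splitting, patch assembly
#' with the mode's class ratio, classifier training, sliding-window
#' detection with the voting rule on a held-out cohort, and
#' participant-level evaluation.  Every artifact is written under
#' `config$out_dir` and stamped with the config hash and seed; any stage
#' failure halts with the stage name and cause.
#'
#' @param config a [pipelineConfig()].
#' @param verbose print stage progress.
#' @return list with the [DiagnosticReport-class], confusion counts,
#'   per-participant findings, the trained classifier and artifact paths.
#' @export
runEndToEnd <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list(logfile = file.path(config$out_dir, "pipeline.log"),
                quiet = !verbose)
  cfg_hash <- object_hash(config)
  seed <- config$seed

  cohort <- run_stage(state, "simulate", makeCohort(
    config$n_train, config$train_prevalence, config$lesion_mix,
    noise_sd = config$noise_sd, seed = child_seed(seed, 11L),
    out_dir = file.path(config$out_dir, "cohort_train"),
    complexity = config$complexity))

  mask_dir <- file.path(config$out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  mask_for <- function(volume, id) {
    f <- file.path(mask_dir, paste0(id, ".nii.gz"))
    if (file.exists(f)) return(readMask(f))
    m <- segmentVessels(volume, ffcmConfig(),
                        min_voxels = config$min_voxels,
                        connectivity = config$connectivity)
    writeVolume(m, f)
    m
  }
  prep <- if (config$use_segmentation) {
    function(volume, id) preprocess_volume(volume, mask_for(volume, id))
  } else {
    function(volume, id) preprocess_volume(volume)
  }

  # split lesioned and healthy participants separately so that every bucket
  # carries both classes (stratified application of the 80/5/15 split)
  split <- run_stage(state, "split", {
    m <- cohort$manifest
    parts <- list(m$participant_id[m$label], m$participant_id[!m$label])
    parts <- parts[vapply(parts, length, 1L) > 0L]
    do.call(rbind, lapply(seq_along(parts), function(i)
      splitParticipants(parts[[i]], seed = child_seed(seed, 17L + i))))
  })
  plan <- samplingPlan(config$mode, ratio = config$ratio,
                       max_offset_mm = config$max_offset_mm,
                       n_offsets = config$n_offsets,
                       seed = child_seed(seed, 19L))
  sets <- run_stage(state, "patches", buildTrainingSet(
    cohort, plan, split, preprocess = prep))
  writePatchManifest(sets, file.path(config$out_dir, "patches.tsv"))
  pipeline_log(state, "patches", "train %d (%d pos), val %d, test %d",
               length(sets$train), sum(patchLabels(sets$train)),
               length(sets$val), length(sets$test))

  model <- buildModel(modelConfig(config$model_preset,
                                  seed = child_seed(seed, 23L)))
  clf <- run_stage(state, "train", trainClassifier(
    model, sets$train, sets$val,
    trainConfig(max_epochs = config$epochs,
                learning_rate = config$learning_rate,
                patience = config$patience,
                batch_size = config$batch_size,
                pos_weight = config$pos_weight,
                seed = child_seed(seed, 29L)),
    verbose = verbose))
  saveCheckpoint(clf, file.path(config$out_dir, "classifier.rds"))

  eval_cohort <- run_stage(state, "simulate-eval", makeCohort(
    config$n_eval, config$eval_prevalence, config$lesion_mix,
    noise_sd = config$noise_sd, seed = child_seed(seed, 31L),
    out_dir = file.path(config$out_dir, "cohort_eval"),
    complexity = config$complexity))

  findings_dir <- file.path(config$out_dir, "findings")
  dir.create(findings_dir, showWarnings = FALSE)
  ids <- eval_cohort$manifest$participant_id
  decisions <- stats::setNames(logical(length(ids)), ids)
  all_findings <- stats::setNames(vector("list", length(ids)), ids)
  run_stage(state, "detect", {
    for (id in ids) {
      vol <- cohortVolume(eval_cohort, id)
      mask <- if (config$use_segmentation)
        segmentVessels(vol, ffcmConfig(), min_voxels = config$min_voxels,
                       connectivity = config$connectivity) else NULL
      roi <- preprocess_volume(vol, mask)
      lat <- slideInfer(clf, roi, mask = mask, stride = config$stride)
      f <- extractFindings(thresholdLattice(lat, config$tau),
                           min_support = config$min_support,
                           connectivity = config$connectivity)
      decisions[[id]] <- participantDecision(f)
      all_findings[[id]] <- f
      jsonlite::write_json(
        list(participant_id = id, config_hash = cfg_hash,
             seed = seed,
             findings = f[, c("component_size", "x_mm", "y_mm", "z_mm")]),
        file.path(findings_dir, paste0(id, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    NULL
  })

  report <- run_stage(state, "eval", {
    truth_lab <- stats::setNames(eval_cohort$manifest$label, ids)
    counts <- confusionCounts(decisions, truth_lab)
    les <- eval_cohort$truth
    strata <- NULL
    if (nrow(les)) {
      detected <- logical(nrow(les))
      for (id in unique(les$participant_id)) {
        sel <- which(les$participant_id == id)
        m <- matchFindingsToTruth(all_findings[[id]],
                                  les[sel, , drop = FALSE],
                                  tol_mm = config$match_tol_mm)
        detected[sel] <- m$detected
      }
      strata <- stratifiedSensitivity(detected, les$kind)
    }
    rep <- diagnosticMetrics(counts, strata = strata,
                             prevalence = config$population_prevalence)
    writeReport(rep, file.path(config$out_dir, "report.json"),
                counts = counts,
                extra = list(config_hash = cfg_hash, seed = seed))
    list(report = rep, counts = counts)
  })

  list(report = report$report, counts = report$counts,
       findings = all_findings, decisions = decisions, classifier = clf,
       history = trainingHistory(clf), config_hash = cfg_hash,
       paths = list(out_dir = config$out_dir,
                    report = file.path(config$out_dir, "report.json"),
                    checkpoint = file.path(config$out_dir, "classifier.rds"),
                    findings = findings_dir))
}
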