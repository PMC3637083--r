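# End-to-end orchestration: simulate -> preprocess -> nu-SVM -> signed
# patterns -> network means -> cut-off models -> statistics report.

#' Pipeline configuration
#'
#' One global seed fans out to per-stage seeds by fixed offsets (simulation:
#' seed; SVM fold draw: seed + 1000; cut-off CV fold draw: seed + 2000), so
#' stages are individually reproducible.  \code{nuGrid} of length 0 skips
#' the grid search and trains at the fixed \code{nu}.
#'
#' @param seed global integer seed (required).
#' @param spec a \linkS4class{SimulationSpec}; defaults to the reference
#'   study conditions with the simulation seed derived from \code{seed}.
#' @param roiBoundsMm reference ROI open bounds in mm.
#' @param smoothFwhmMm smoothing FWHM in mm (default 12).
#' @param nu fixed nu when no grid search is run.
#' @param nuGrid candidate nu values for the grid search (default: none).
#' @param percentile |w| percentile for pattern extraction (default 90).
#' @param outputDir directory for artifacts (created if missing).
#' @return A named list (class "petmvpaConfig") that round-trips losslessly
#'   through YAML via \code{\link{writePipelineConfig}}.
#' @export
pipelineConfig <- function(seed, spec = NULL,
                           roiBoundsMm = c(-8, 8, -16, -8, -34, -24),
                           smoothFwhmMm = 12, nu = 0.5, nuGrid = numeric(0),
                           percentile = 90, outputDir = tempfile("petmvpa_")) {
  if (missing(seed)) stop("seed is mandatory")
  seed <- as.integer(seed)
  if (is.null(spec)) spec <- simulationSpec(seed = seed)
  cfg <- list(seed = seed, spec = spec, roiBoundsMm = roiBoundsMm,
              smoothFwhmMm = smoothFwhmMm, nu = nu, nuGrid = nuGrid,
              percentile = percentile, outputDir = outputDir)
  class(cfg) <- "petmvpaConfig"
  cfg
}

.specAsList <- function(spec) {
  list(gridShape = spec@gridShape, voxelSizeMm = spec@voxelSizeMm,
       nPerGroup = spec@nPerGroup, ageRange = spec@ageRange,
       globalAgeSlope = spec@globalAgeSlope,
       networkAgeGain = spec@networkAgeGain, chtEffect = spec@chtEffect,
       noiseSd = spec@noiseSd, psfFwhmMm = spec@psfFwhmMm, seed = spec@seed)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg a configuration from \code{\link{pipelineConfig}}.
#' @param file YAML path.
#' @return \code{writePipelineConfig}: the path, invisibly;
#'   \code{readPipelineConfig}: the configuration.
#' @export
writePipelineConfig <- function(cfg, file) {
  out <- cfg
  out$spec <- .specAsList(cfg$spec)
  class(out) <- NULL
  yaml::write_yaml(out, file)
  invisible(file)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(file) {
  raw <- yaml::read_yaml(file)
  spec <- do.call(simulationSpec, raw$spec)
  pipelineConfig(seed = raw$seed, spec = spec,
                 roiBoundsMm = as.numeric(raw$roiBoundsMm),
                 smoothFwhmMm = raw$smoothFwhmMm, nu = raw$nu,
                 nuGrid = as.numeric(raw$nuGrid), percentile = raw$percentile,
                 outputDir = raw$outputDir)
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, preprocesses it (smooth, then reference-normalize),
#' trains the whole-brain linear nu-SVM (optionally grid-searching nu),
#' cross-validates it leave-pair-out, extracts the signed weight patterns,
#' computes per-subject network means, fits single and floating cut-off
#' models (in-sample and leave-pair-out CV accuracies), and computes the
#' supporting statistics.  All artifacts are written under
#' \code{cfg$outputDir}; an identical seed reproduces a byte-identical
#' summary file.
#'
#' Which signed pattern corresponds to the clinical PCS is decided post
#' hoc: the side whose group t test shows the lower p value with the CHT
#' mean below the no-CHT mean is reported as \code{pcs_pattern_sign}.
#'
#' @param cfg a configuration from \code{\link{pipelineConfig}}.
#' @param writeVolumes write per-subject NIfTI volumes (default TRUE; the
#'   summary does not depend on it).
#' @return A list with \code{summary} (named numerics), \code{paths},
#'   \code{networkMeans}, \code{models}, and the fitted objects, invisibly.
#' @export
runPipeline <- function(cfg, writeVolumes = TRUE) {
  stopifnot(inherits(cfg, "petmvpaConfig"))
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(cfg$outputDir))
    stop(sprintf("cannot create output directory %s", cfg$outputDir))
  paths <- list(summary = file.path(cfg$outputDir, "summary.json"),
                covariates = file.path(cfg$outputDir, "covariates.tsv"),
                networkMeans = file.path(cfg$outputDir, "network_means.tsv"),
                models = file.path(cfg$outputDir, "cutoff_models.json"),
                stats = file.path(cfg$outputDir, "group_stats.tsv"),
                weightMap = file.path(cfg$outputDir, "weight_map.nii.gz"),
                cvReport = file.path(cfg$outputDir, "cv_report.tsv"))

  # --- simulate -------------------------------------------------------
  sim <- simulateCohort(cfg$spec)
  cohort <- sim$cohort; masks <- sim$masks
  vs <- cfg$spec@voxelSizeMm
  writeCovariates(cohort, paths$covariates)
  for (nm in c("brain", "pcs", "dan", "reference"))
    writeMask(slot(masks, nm),
              file.path(cfg$outputDir, sprintf("mask_%s.nii.gz", nm)), vs)
  if (writeVolumes)
    for (id in names(cohort@volumes))
      writeVolume(cohort@volumes[[id]],
                  file.path(cfg$outputDir, sprintf("%s.nii.gz", id)))

  # --- preprocess -----------------------------------------------------
  roi <- referenceROI(cfg$roiBoundsMm)
  pre <- preprocessCohort(cohort, roi, cfg$smoothFwhmMm)

  # --- MVPA -----------------------------------------------------------
  fm <- buildFeatureMatrix(pre, masks@brain)
  cvSeed <- cfg$seed + 1000L
  if (length(cfg$nuGrid) > 0) {
    gs <- gridSearchNu(fm, cfg$nuGrid, seed = cvSeed)
    nu <- gs$bestNu
  } else {
    gs <- NULL
    nu <- cfg$nu
  }
  cv <- crossValidate(fm, nu, seed = cvSeed)
  wm <- trainNuSvm(fm, nu)
  writeWeightMap(wm, paths$weightMap, vs)
  utils::write.table(cvFolds(cv), paths$cvReport, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- patterns and network means ------------------------------------
  patterns <- extractSignedPatterns(wm, cfg$percentile)
  writeMask(patterns@positiveMask,
            file.path(cfg$outputDir, "pattern_positive.nii.gz"), vs)
  writeMask(patterns@negativeMask,
            file.path(cfg$outputDir, "pattern_negative.nii.gz"), vs)
  nm <- cohortNetworkMeans(pre, patterns)
  utils::write.table(nm, paths$networkMeans, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cht <- nm$group == "CHT"
  tPos <- twoSampleT(nm$pcs_mean[!cht], nm$pcs_mean[cht])
  tNeg <- twoSampleT(nm$dan_mean[!cht], nm$dan_mean[cht])
  # post-hoc: the group-difference side (CHT below no-CHT, smaller p)
  posIsPcs <- (estimate(tPos) > 0) &&
    (estimate(tNeg) <= 0 || pValue(tPos) <= pValue(tNeg))
  pcsSign <- if (posIsPcs) "positive" else "negative"

  # --- cut-off models -------------------------------------------------
  labels <- ifelse(cht, -1, 1)
  coSeed <- cfg$seed + 2000L
  singlePcs <- bestSingleCutoff(nm$pcs_mean, labels, "pcs")
  singleDan <- bestSingleCutoff(nm$dan_mean, labels, "dan")
  floating <- bestFloatingCutoff(nm$dan_mean, nm$pcs_mean, labels)
  cvPcs <- cutoffCrossValidate(nm$dan_mean, nm$pcs_mean, labels, "pcs",
                               seed = coSeed)
  cvDan <- cutoffCrossValidate(nm$dan_mean, nm$pcs_mean, labels, "dan",
                               seed = coSeed)
  cvFloat <- cutoffCrossValidate(nm$dan_mean, nm$pcs_mean, labels, "floating",
                                 seed = coSeed)
  models <- list(
    single_pcs = cutoffModelAsList(singlePcs$model, singlePcs$accuracy,
                                   cvAccuracy(cvPcs)),
    single_dan = cutoffModelAsList(singleDan$model, singleDan$accuracy,
                                   cvAccuracy(cvDan)),
    floating = cutoffModelAsList(floating$model, floating$accuracy,
                                 cvAccuracy(cvFloat)))
  jsonlite::write_json(models, paths$models, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  # --- statistics -----------------------------------------------------
  corPcsDan <- pearsonR(nm$pcs_mean, nm$dan_mean)
  corAgePcs <- pearsonR(nm$age, nm$pcs_mean)
  corAgeDan <- pearsonR(nm$age, nm$dan_mean)
  anc <- ancovaGroup(nm$pcs_mean, nm$group, nm$age)
  statTab <- data.frame(
    test = c("pcs_t", "dan_t", "pcs_dan_pearson", "age_pcs_pearson",
             "age_dan_pearson", "ancova_pcs_group_age"),
    statistic = c(statistic(tPos), statistic(tNeg), statistic(corPcsDan),
                  statistic(corAgePcs), statistic(corAgeDan), statistic(anc)),
    estimate = c(estimate(tPos), estimate(tNeg), estimate(corPcsDan),
                 estimate(corAgePcs), estimate(corAgeDan), estimate(anc)),
    p_value = c(pValue(tPos), pValue(tNeg), pValue(corPcsDan),
                pValue(corAgePcs), pValue(corAgeDan), pValue(anc)))
  utils::write.table(statTab, paths$stats, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  dicePcs <- diceCoefficient(
    if (posIsPcs) patterns@positiveMask else patterns@negativeMask,
    masks@pcs)
  summary <- list(
    n_subjects = nSubjects(cohort),
    nu = nu,
    cv_accuracy = cvAccuracy(cv),
    pcs_pattern_sign = pcsSign,
    pcs_t_p = pValue(tPos), dan_t_p = pValue(tNeg),
    single_pcs_accuracy = singlePcs$accuracy,
    single_dan_accuracy = singleDan$accuracy,
    floating_accuracy = floating$accuracy,
    single_pcs_cv_accuracy = cvAccuracy(cvPcs),
    single_dan_cv_accuracy = cvAccuracy(cvDan),
    floating_cv_accuracy = cvAccuracy(cvFloat),
    dice_pcs = dicePcs,
    r_pcs_dan = estimate(corPcsDan),
    r_age_pcs = estimate(corAgePcs),
    r_age_dan = estimate(corAgeDan),
    ancova_age_r2 = anc@r.squared,
    ancova_age_group_p = pValue(anc))
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(summary = summary, paths = paths, networkMeans = nm,
                 models = models, cohort = cohort, masks = masks,
                 weightMap = wm, patterns = patterns, cv = cv,
                 gridSearch = gs))
}
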