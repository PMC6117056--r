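#' Run configuration for the end-to-end pipeline
#'
#' One seed governs the whole run; stage configs inherit it. Any element
#' of the `cohort`, `ct`, or `oemri` lists overrides the corresponding
#' argument of [cohortConfig()], [ctPhantomConfig()], or
#' [oemriPhantomConfig()].
#'
#' @param seed global integer seed.
#' @param cohort,ct,oemri named lists of config overrides.
#' @param imageGrid CT phantom grid for per-subject images.
#' @param verbose print per-stage progress.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(seed = 1L, cohort = list(), ct = list(),
                      oemri = list(), imageGrid = c(24L, 24L, 30L),
                      verbose = TRUE) {
  cfg <- list(seed = as.integer(seed), cohort = cohort, ct = ct,
              oemri = oemri, imageGrid = as.integer(imageGrid),
              verbose = verbose)
  class(cfg) <- "RunConfig"
  cfg
}

stageLog <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[lunghetero] %s", sprintf(fmt, ...)))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates generate -> CT densitometry -> OEMRI quantification ->
#' cohort statistics and writes a reproducible bundle under `outDir`:
#' the serialized run config, per-subject phantom images, the cohort CSV,
#' per-subject LAV/RER result JSON, and the statistics report
#' (group comparison of every imaging index, the index correlation
#' pairs, and stepwise regressions of FEV1, DL_CO and PaO2 on the CT and
#' the MRI candidate sets within the COPD group). Re-running with the
#' same config writes byte-identical CSV/JSON outputs.
#'
#' Stages can be run singly via `stages`, provided earlier stage outputs
#' already exist in `outDir`: `"synth"` writes phantoms and ground truth,
#' `"ct-quant"` and `"oemri-quant"` (re)measure the per-subject images,
#' `"stats"` consumes the measured cohort table.
#'
#' @param config a [runConfig()].
#' @param outDir output directory (created if needed).
#' @param stages character subset of
#'   `c("synth", "ct-quant", "oemri-quant", "stats")`; default all.
#' @return invisibly, a list with the cohort table, per-subject results,
#'   and the statistics report.
#' @export
runPipeline <- function(config, outDir,
                        stages = c("synth", "ct-quant", "oemri-quant",
                                   "stats")) {
  stopifnot(inherits(config, "RunConfig"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  jsonWrite(unclass(config), file.path(outDir, "run_config.json"))
  v <- config$verbose

  tablePath <- file.path(outDir, "cohort.csv")
  truthPath <- file.path(outDir, "cohort_truth.csv")

  if ("synth" %in% stages) {
    stageLog(v, "stage synth: generating cohort")
    cohCfg <- do.call(cohortConfig, c(list(seed = config$seed),
                                      config$cohort))
    coh <- generateCohort(cohCfg)
    utils::write.csv(coh$truth, truthPath, row.names = FALSE)
    writeCohortTable(coh$table, tablePath)
    for (i in seq_len(nrow(coh$table))) {
      id <- coh$table$id[i]
      subSeed <- (config$seed + 7919L * i) %% 2147483647L
      sdir <- file.path(outDir, "subjects", id)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      ctCfg <- do.call(ctPhantomConfig, c(list(
        gridShape = config$imageGrid,
        lavFractionTarget = coh$truth$lav_fraction[i],
        gradientStrength = coh$truth$gradient[i],
        seed = subSeed), config$ct))
      ct <- generateCTPhantom(ctCfg)
      writeCTVolume(ct$volume, file.path(sdir, "ct"))
      mrCfg <- do.call(oemriPhantomConfig, c(list(
        enhancementAmplitudeMean = coh$truth$mrer_true[i] / 100,
        enhancementGradient = 0.3 * coh$truth$gradient[i],
        seed = subSeed), config$oemri))
      mr <- generateOEMRIPhantom(mrCfg, truth = ct$truth)
      writeOEMRISeries(mr$series, file.path(sdir, "oemri"))
      stageLog(v, "  %s: phantoms written", id)
    }
  }

  if (!file.exists(tablePath))
    stop("no cohort table in ", outDir, "; run the synth stage first")
  tab <- readCohortTable(tablePath)
  subjects <- tab$id

  measureStage <- function(name, fn, cols) {
    for (id in subjects) {
      sdir <- file.path(outDir, "subjects", id)
      res <- tryCatch(fn(sdir),
                      error = function(e) stop(sprintf(
                        "stage %s failed for subject %s: %s",
                        name, id, conditionMessage(e)), call. = FALSE))
      for (cn in names(res$cols)) tab[tab$id == id, cn] <<- res$cols[[cn]]
      jsonWrite(res$json, file.path(sdir, paste0(name, ".json")))
    }
    writeCohortTable(tab, tablePath)
  }

  if ("ct-quant" %in% stages) {
    stageLog(v, "stage ct-quant: %d subjects", length(subjects))
    measureStage("ct-quant", function(sdir) {
      vol <- readCTVolume(file.path(sdir, "ct"))
      lav <- ctDensitometry(vol)
      list(cols = list(lav_pct = lavPercent(lav), sd_lav = sdLav(lav)),
           json = list(lav_percent_whole = lavPercent(lav),
                       per_partition = perPartition(lav),
                       sd_lav = sdLav(lav),
                       threshold = lav@threshold,
                       calibration_shift = calibrationShift(lav)))
    })
  }

  if ("oemri-quant" %in% stages) {
    stageLog(v, "stage oemri-quant: %d subjects", length(subjects))
    measureStage("oemri-quant", function(sdir) {
      ser <- readOEMRISeries(file.path(sdir, "oemri"))
      rer <- rerAnalysis(ser)
      list(cols = list(mrer = mrer(rer), sd_rer = sdRer(rer)),
           json = list(mrer = mrer(rer), sd_rer = sdRer(rer),
                       per_partition = perPartition(rer),
                       excluded_pixels = rer@excludedPixels))
    })
  }

  report <- NULL
  if ("stats" %in% stages) {
    stageLog(v, "stage stats")
    tab <- readCohortTable(tablePath)
    copd <- tab[tab$group == "COPD", , drop = FALSE]
    imaging <- c("lav_pct", "sd_lav", "mrer", "sd_rer")
    comparisons <- lapply(imaging, function(vn) {
      gc <- compareGroups(tab, vn)
      list(variable = vn, test = gc$test, p.value = gc$p.value,
           copd_mean = gc$copd$mean, control_mean = gc$control$mean,
           copd_median = gc$copd$median, control_median = gc$control$median)
    })
    corPairs <- list(c("lav_pct", "mrer"), c("sd_lav", "sd_rer"),
                     c("lav_pct", "dlco"), c("mrer", "dlco"),
                     c("sd_lav", "pao2"), c("mrer", "pao2"))
    correlations <- lapply(corPairs, function(p) {
      cr <- correlateVars(copd, p[1], p[2])
      list(x = p[1], y = p[2], r = cr$r, p.value = cr$p.value,
           method = cr$method)
    })
    regress <- function(outcome, cands) {
      rr <- stepwiseRegression(copd, outcome, cands)
      list(outcome = outcome, candidates = cands,
           selected = rr$selected, r.squared = rr$r.squared)
    }
    regressions <- list(
      ct_fev1 = regress("fev1_l", c("age", "bmi", "lav_pct", "sd_lav")),
      ct_dlco = regress("dlco", c("age", "bmi", "lav_pct", "sd_lav")),
      ct_pao2 = regress("pao2", c("age", "bmi", "lav_pct", "sd_lav")),
      mri_fev1 = regress("fev1_l", c("age", "bmi", "mrer", "sd_rer")),
      mri_dlco = regress("dlco", c("age", "bmi", "mrer", "sd_rer")),
      mri_pao2 = regress("pao2", c("age", "bmi", "mrer", "sd_rer")))
    report <- list(group_comparisons = comparisons,
                   correlations = correlations,
                   stepwise = regressions)
    jsonWrite(report, file.path(outDir, "stats_report.json"))
  }

  stageLog(v, "done")
  invisible(list(table = tab, report = report))
}
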