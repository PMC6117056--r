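#' Configuration for the synthetic COPD/control cohort
#'
#' Describes the study design emulated by [generateCohort()]: a COPD group
#' and a healthy control group whose imaging ground truth (emphysema
#' fraction, cranial-caudal gradient, oxygen-enhancement level) is drawn
#' from group-specific distributions, and whose clinical covariates are
#' linear functions of that ground truth plus Gaussian noise. Default
#' group sizes are 40 COPD and 9 controls, and the default group MRER
#' distributions are 12.6 +/- 4.4% (COPD) versus 22.0 +/- 3.4% (control).
#'
#' Covariate link model (per subject, before noise):
#' \itemize{
#'   \item FEV1 (L) `= 4.0 - 7 * lavFrac`
#'   \item DL_CO (mL/min/mmHg) `= 30 - 55 * lavFrac`
#'   \item PaO2 (Torr) `= 88 - 25 * gradient`
#'   \item RV/TLC (%) `= 28 + 35 * lavFrac`
#'   \item SD-LAV (%) `= 0.5 + 15 * gradient` (SD-LAV is the gradient's
#'     observable proxy)
#'   \item SD-RER (%) `= 1.5 + 6 * gradient`
#' }
#'
#' @param nCOPD,nControl group sizes (each at least 2).
#' @param lavFracMean,lavFracSD numeric(2) `(copd, control)` emphysema
#'   fraction distribution; draws are clipped to `[0.001, 0.55]`.
#' @param gradientMean,gradientSD numeric(2) cranial-caudal gradient
#'   distribution; clipped to `[0, 0.9]`.
#' @param mrerMean,mrerSD numeric(2) group MRER (%) distribution.
#' @param links named list of linear link coefficients
#'   `c(intercept, slope)`; see Details for which ground-truth variable
#'   each slope multiplies.
#' @param noiseSD named list of additive noise SDs; set all to 0 for the
#'   deterministic limit where covariates equal their linear predictors.
#' @param ageMean,ageSD,bmiMean,bmiSD numeric(2) group demographics.
#' @param seed integer generator seed.
#' @return a named list of class `CohortConfig`.
#' @export
cohortConfig <- function(nCOPD = 40L, nControl = 9L,
                         lavFracMean = c(0.28, 0.02),
                         lavFracSD = c(0.10, 0.01),
                         gradientMean = c(0.40, 0.10),
                         gradientSD = c(0.20, 0.05),
                         mrerMean = c(12.6, 22.0),
                         mrerSD = c(4.4, 3.4),
                         links = list(fev1 = c(4.0, -7),
                                      dlco = c(30, -55),
                                      pao2 = c(88, -25),
                                      rvtlc = c(28, 35),
                                      sdlav = c(0.5, 15),
                                      sdrer = c(1.5, 6)),
                         noiseSD = list(fev1 = 0.35, dlco = 2.5, pao2 = 4,
                                        rvtlc = 3, sdlav = 0.5, sdrer = 0.6,
                                        lavPct = 0.5, fvc = 0.3, paco2 = 2),
                         ageMean = c(70.5, 34), ageSD = c(7, 4),
                         bmiMean = c(21.5, 20.9), bmiSD = c(2.2, 1.8),
                         seed = 1L) {
  cfg <- as.list(environment())
  cfg$nCOPD <- as.integer(nCOPD); cfg$nControl <- as.integer(nControl)
  cfg$seed <- as.integer(seed)
  if (cfg$nCOPD < 2L || cfg$nControl < 2L)
    stop("both groups need at least 2 subjects")
  if (any(unlist(cfg$noiseSD) < 0)) stop("noise SDs must be non-negative")
  stopifnot(all(c("fev1", "dlco", "pao2", "rvtlc", "sdlav", "sdrer") %in%
                names(cfg$links)))
  class(cfg) <- "CohortConfig"
  cfg
}

clipNorm <- function(n, mean, sd, lo, hi)
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

#' Generate a synthetic cohort with linked covariates and ground truth
#'
#' Draws per-subject imaging ground truth from the group distributions in
#' the config, derives clinical covariates through the linear link model,
#' and adds Gaussian noise. With `images = TRUE` a CT phantom and an
#' oxygen-enhanced MRI phantom are additionally generated per subject
#' (ground truth driving both), measured with [ctDensitometry()] and
#' [rerAnalysis()], and the measured imaging indices replace the
#' noise-model ones in the table; the phantom files are written under
#' `dir` when given.
#'
#' @param config a [cohortConfig()].
#' @param images also generate and measure per-subject image pairs
#'   (slower; used by the pipeline demo).
#' @param imageGrid CT grid shape when `images = TRUE`.
#' @param dir optional output directory for per-subject phantom files.
#' @return list with `table` (a cohort data.frame, one row per subject)
#'   and `truth` (data.frame of the per-subject ground-truth draws and
#'   noiseless covariate means).
#' @examples
#' coh <- generateCohort(cohortConfig(nCOPD = 10, nControl = 4, seed = 2))
#' head(coh$table)
#' @export
generateCohort <- function(config, images = FALSE,
                           imageGrid = c(24L, 24L, 30L), dir = NULL) {
  stopifnot(inherits(config, "CohortConfig"))
  n <- config$nCOPD + config$nControl
  g <- rep(c(1L, 2L), c(config$nCOPD, config$nControl))  # 1 COPD, 2 control
  ns <- config$noiseSD
  noise <- function(sd) if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)

  out <- withr::with_seed(config$seed, {
    lavFrac <- clipNorm(n, config$lavFracMean[g], config$lavFracSD[g],
                        0.001, 0.55)
    gradient <- clipNorm(n, config$gradientMean[g], config$gradientSD[g],
                         0, 0.9)
    mrerTrue <- pmax(stats::rnorm(n, config$mrerMean[g], config$mrerSD[g]), 0)
    age <- clipNorm(n, config$ageMean[g], config$ageSD[g], 18, 95)
    bmi <- clipNorm(n, config$bmiMean[g], config$bmiSD[g], 14, 40)

    L <- config$links
    fev1Mean <- L$fev1[1] + L$fev1[2] * lavFrac
    dlcoMean <- L$dlco[1] + L$dlco[2] * lavFrac
    pao2Mean <- L$pao2[1] + L$pao2[2] * gradient
    rvtlcMean <- L$rvtlc[1] + L$rvtlc[2] * lavFrac
    sdlavMean <- L$sdlav[1] + L$sdlav[2] * gradient
    sdrerMean <- L$sdrer[1] + L$sdrer[2] * gradient

    fev1 <- pmax(fev1Mean + noise(ns$fev1), 0.3)
    fvc <- fev1 + 1.3 + noise(ns$fvc)
    predFev1 <- 4.6 - 0.025 * age  # crude age-based predicted FEV1
    tab <- data.frame(
      id = sprintf("S%03d", seq_len(n)),
      group = c("COPD", "control")[g],
      age = age, bmi = bmi,
      fev1_l = fev1,
      pct_fev1 = 100 * fev1 / predFev1,
      fvc_l = fvc, vc_l = fvc + 0.05,
      rv_tlc = pmax(rvtlcMean + noise(ns$rvtlc), 15),
      dlco = pmax(dlcoMean + noise(ns$dlco), 2),
      pao2 = pao2Mean + noise(ns$pao2),
      paco2 = 39.5 + noise(ns$paco2),
      lav_pct = pmin(pmax(100 * lavFrac + noise(ns$lavPct), 0), 100),
      sd_lav = pmax(sdlavMean + noise(ns$sdlav), 0),
      mrer = mrerTrue,
      sd_rer = pmax(sdrerMean + noise(ns$sdrer), 0),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      id = tab$id, group = tab$group,
      lav_fraction = lavFrac, gradient = gradient, mrer_true = mrerTrue,
      fev1_mean = fev1Mean, dlco_mean = dlcoMean, pao2_mean = pao2Mean,
      rv_tlc_mean = rvtlcMean, sd_lav_mean = sdlavMean,
      sd_rer_mean = sdrerMean, stringsAsFactors = FALSE
    )
    list(table = tab, truth = truth)
  })

  if (images) {
    for (i in seq_len(n)) {
      subSeed <- (config$seed + 7919L * i) %% 2147483647L
      ct <- generateCTPhantom(ctPhantomConfig(
        gridShape = imageGrid,
        lavFractionTarget = out$truth$lav_fraction[i],
        gradientStrength = out$truth$gradient[i],
        seed = subSeed))
      mr <- generateOEMRIPhantom(oemriPhantomConfig(
        enhancementAmplitudeMean = out$truth$mrer_true[i] / 100,
        enhancementGradient = 0.3 * out$truth$gradient[i],
        seed = subSeed), truth = ct$truth)
      lav <- ctDensitometry(ct$volume)
      rer <- rerAnalysis(mr$series)
      out$table$lav_pct[i] <- lavPercent(lav)
      out$table$sd_lav[i] <- sdLav(lav)
      out$table$mrer[i] <- mrer(rer)
      out$table$sd_rer[i] <- sdRer(rer)
      if (!is.null(dir)) {
        sdir <- file.path(dir, out$table$id[i])
        dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
        writeCTVolume(ct$volume, file.path(sdir, "ct"))
        writeOEMRISeries(mr$series, file.path(sdir, "oemri"))
      }
    }
  }
  out
}
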