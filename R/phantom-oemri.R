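#' Configuration for the synthetic oxygen-enhanced MRI phantom
#'
#' Parameters of the oxygen wash-in signal model used by
#' [generateOEMRIPhantom()]. The exam emulated is the standard protocol:
#' room air breathing, then 100% oxygen, then room air again, each phase
#' lasting five minutes, imaged as repeated coronal T1-weighted frames on
#' three sections.
#'
#' @param sectionCount number of coronal sections (default 3:
#'   anterior, central, posterior).
#' @param frameShape integer(2), pixels (rows, cols); rows run cranial to
#'   caudal.
#' @param framesPerPhase frames acquired during each phase.
#' @param phaseDurations numeric(3), minutes of (air1, O2, air2);
#'   default `c(5, 5, 5)`.
#' @param enhancementAmplitudeMean mean fractional signal enhancement at
#'   the oxygen steady state (e.g. 0.22 means +22%).
#' @param enhancementGradient cranial-caudal linear tilt of the amplitude,
#'   in `[-1, 1]`; 0 is homogeneous.
#' @param washinTimeConstant exponential wash-in/wash-out time constant,
#'   in frames.
#' @param noiseSD additive Gaussian noise SD, signal units.
#' @param baselineSignal room-air baseline signal level.
#' @param seed integer generator seed.
#' @return a named list of class `OEMRIPhantomConfig`.
#' @export
oemriPhantomConfig <- function(sectionCount = 3L,
                               frameShape = c(48L, 40L),
                               framesPerPhase = 30L,
                               phaseDurations = c(5, 5, 5),
                               enhancementAmplitudeMean = 0.22,
                               enhancementGradient = 0,
                               washinTimeConstant = 5,
                               noiseSD = 2,
                               baselineSignal = 100,
                               seed = 1L) {
  cfg <- list(sectionCount = as.integer(sectionCount),
              frameShape = as.integer(frameShape),
              framesPerPhase = as.integer(framesPerPhase),
              phaseDurations = as.numeric(phaseDurations),
              enhancementAmplitudeMean = enhancementAmplitudeMean,
              enhancementGradient = enhancementGradient,
              washinTimeConstant = washinTimeConstant,
              noiseSD = noiseSD, baselineSignal = baselineSignal,
              seed = as.integer(seed))
  if (cfg$sectionCount < 1L) stop("sectionCount must be at least 1")
  if (cfg$framesPerPhase < 1L) stop("framesPerPhase must be at least 1")
  if (length(cfg$phaseDurations) != 3L || any(cfg$phaseDurations <= 0))
    stop("phaseDurations must be three positive durations (minutes)")
  if (cfg$enhancementAmplitudeMean < 0)
    stop("enhancementAmplitudeMean must be non-negative")
  if (abs(cfg$enhancementGradient) > 1)
    stop("enhancementGradient must lie in [-1, 1]")
  if (cfg$washinTimeConstant <= 0) stop("washinTimeConstant must be positive")
  if (cfg$noiseSD < 0) stop("noiseSD must be non-negative")
  class(cfg) <- "OEMRIPhantomConfig"
  cfg
}

# Oxygen wash-in curve w(t) per frame: 0 during air1, exponential rise
# with the stated time constant during O2, exponential decay during air2.
washinCurve <- function(framesPerPhase, tau) {
  k <- seq_len(framesPerPhase)
  rise <- 1 - exp(-k / tau)
  wEnd <- rise[framesPerPhase]
  decay <- wEnd * exp(-k / tau)
  c(rep(0, framesPerPhase), rise, decay)
}

# Elliptical two-lung ROI on a coronal section.
coronalLungROI <- function(frameShape) {
  r <- (seq_len(frameShape[1]) - 0.5) / frameShape[1]
  c <- (seq_len(frameShape[2]) - 0.5) / frameShape[2]
  R <- matrix(r, frameShape[1], frameShape[2])
  C <- matrix(c, frameShape[1], frameShape[2], byrow = TRUE)
  (((C - 0.28) / 0.20)^2 + ((R - 0.5) / 0.42)^2 <= 1) |
    (((C - 0.72) / 0.20)^2 + ((R - 0.5) / 0.42)^2 <= 1)
}

#' Generate a synthetic oxygen-enhanced MRI series with known amplitudes
#'
#' Per-pixel signal follows
#' `S(t) = baseline * (1 + a * w(t)) + noise`, where `a` is the pixel's
#' true enhancement amplitude and `w(t)` is 0 while breathing room air,
#' rises as `1 - exp(-t/tau)` during oxygen, and decays exponentially
#' after the switch back to air. The amplitude field has the configured
#' mean, a linear cranial-caudal tilt, and — when CT ground truth is
#' supplied — a local reduction proportional to the emphysema fraction of
#' the matching cranial-caudal level, emulating lost oxygen uptake in
#' destroyed parenchyma. Negative signals after noise are clipped to zero
#' and the clipped count is reported via a message.
#'
#' @param config an [oemriPhantomConfig()].
#' @param truth optional [PhantomTruth-class] from [generateCTPhantom()];
#'   couples the amplitude field to the emphysema distribution.
#' @return list with `series` (an [OEMRISeries-class]) and `truth` (a
#'   [PhantomTruth-class] whose `amplitudeTrue` holds the per-pixel
#'   amplitude matrices).
#' @export
generateOEMRIPhantom <- function(config, truth = NULL) {
  stopifnot(inherits(config, "OEMRIPhantomConfig"))
  fs <- config$frameShape
  nFrames <- 3L * config$framesPerPhase
  w <- washinCurve(config$framesPerPhase, config$washinTimeConstant)
  roi <- coronalLungROI(fs)

  # cranial-caudal amplitude tilt over pixel rows
  u <- if (fs[1] > 1) 2 * (seq_len(fs[1]) - 1) / (fs[1] - 1) - 1 else 0
  rowAmp <- config$enhancementAmplitudeMean *
    pmax(1 + config$enhancementGradient * u, 0)

  # emphysema coupling: amplitude scaled by the non-emphysematous tissue
  # fraction of the matching cranial-caudal level of the CT ground truth
  reduction <- rep(1, fs[1])
  if (!is.null(truth)) {
    stopifnot(is(truth, "PhantomTruth"))
    lab <- truth@emphysemaLabel
    nz <- dim(lab)[3]
    # in-slice emphysema fraction; the factor 3 approximates the
    # slice-to-lung area ratio so reduction tracks the in-lung fraction
    sliceFrac <- vapply(seq_len(nz), function(k) mean(lab[, , k]), numeric(1))
    zmap <- pmin(pmax(round(seq_len(fs[1]) / fs[1] * nz), 1L), nz)
    reduction <- pmax(1 - 3 * sliceFrac[zmap], 0)
  }
  amp <- matrix(rowAmp * reduction, fs[1], fs[2])

  locations <- c("anterior", "central", "posterior",
                 paste0("section", seq_len(max(0, config$sectionCount - 3L)) + 3L)
                 )[seq_len(config$sectionCount)]
  clipped <- 0L
  sectionsList <- withr::with_seed(config$seed, {
    lapply(seq_len(config$sectionCount), function(s) {
      frames <- array(0, dim = c(fs[1], fs[2], nFrames))
      for (t in seq_len(nFrames)) {
        st <- config$baselineSignal * (1 + amp * w[t])
        if (config$noiseSD > 0)
          st <- st + matrix(stats::rnorm(prod(fs), 0, config$noiseSD),
                            fs[1], fs[2])
        neg <- st < 0
        if (any(neg)) {
          clipped <<- clipped + sum(neg)
          st[neg] <- 0
        }
        frames[, , t] <- st
      }
      list(frames = frames, spacing = c(4, 4),
           zcoord = (seq_len(fs[1]) - 0.5) * 4,
           roi = roi)
    })
  })
  if (clipped > 0L)
    message(sprintf("clipped %d negative signal values to 0", clipped))

  labels <- factor(rep(c("air1", "O2", "air2"), each = config$framesPerPhase),
                   levels = c("air1", "O2", "air2"))
  series <- methods::new("OEMRISeries", sections = sectionsList,
                         phaseLabels = labels,
                         sectionLocations = locations,
                         phaseDurations = config$phaseDurations)
  outTruth <- if (is.null(truth))
    methods::new("PhantomTruth", emphysemaLabel = array(FALSE, c(1, 1, 1)),
                 lavFractionWhole = 0, lavFractionPerPartition = numeric())
  else truth
  outTruth@amplitudeTrue <- rep(list(amp), config$sectionCount)
  list(series = series, truth = outTruth)
}
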