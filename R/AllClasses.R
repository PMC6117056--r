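#' @import methods
NULL

#' CTVolume: a calibrated-or-raw HU voxel grid with lung and trachea masks
#'
#' The substrate of all CT densitometry. Voxel values are Hounsfield units
#' (air about -1000, water 0). The third array index is the cranial-caudal
#' slice axis with index 1 the most cranial slice; readers enforce this
#' convention so the sign of any cranial-caudal gradient is unambiguous.
#'
#' @slot hu 3-D numeric array of HU values, dimensions (x, y, z).
#' @slot spacing numeric(3), voxel edge length in mm per axis (x, y, z).
#' @slot lungMask logical array congruent with `hu`; TRUE inside lung
#'   parenchyma (trachea excluded).
#' @slot tracheaMask logical array congruent with `hu`; TRUE inside the
#'   tracheal air column used for HU calibration.
#' @slot calibrationShift numeric(1), additive HU shift already applied
#'   (0 for a raw volume).
#'
#' @seealso [calibrateHU()], [lavMask()], [partitionIsovolumetric()]
#' @export
setClass("CTVolume",
  representation(
    hu = "array",
    spacing = "numeric",
    lungMask = "array",
    tracheaMask = "array",
    calibrationShift = "numeric"
  ),
  prototype(calibrationShift = 0)
)

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@hu)) != 3L)
    msg <- c(msg, "hu must be a 3-D array")
  if (!identical(dim(object@hu), dim(object@lungMask)) ||
      !identical(dim(object@hu), dim(object@tracheaMask)))
    msg <- c(msg, "masks must be congruent in shape with hu")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive mm values")
  if (!is.logical(object@lungMask) || !is.logical(object@tracheaMask))
    msg <- c(msg, "masks must be logical arrays")
  if (is.logical(object@lungMask) && is.logical(object@tracheaMask) &&
      identical(dim(object@lungMask), dim(object@tracheaMask)) &&
      any(object@lungMask & object@tracheaMask))
    msg <- c(msg, "lungMask and tracheaMask must be disjoint")
  if (is.logical(object@lungMask) && sum(object@lungMask) < 12L)
    msg <- c(msg, "lung mask must contain at least 12 voxels (partitionable)")
  if (length(msg)) msg else TRUE
})

#' OEMRISeries: oxygen-enhanced MRI signal-intensity time series
#'
#' Holds the coronal 2-D frame stacks of an oxygen-enhanced MRI exam
#' (typically three sections: anterior, central, posterior). Each frame is
#' labelled with its acquisition phase: room air (`air1`), 100% oxygen
#' (`O2`), room air again (`air2`). Pixel rows run cranial to caudal; the
#' per-row physical coordinate map lets partitions pool pixels across
#' sections on a common cranial-caudal axis.
#'
#' @slot sections list; each element a list with components `frames`
#'   (numeric array rows x cols x frames), `spacing` (numeric(2) mm),
#'   `zcoord` (numeric, cranial-caudal mm coordinate per pixel row,
#'   increasing caudal), and `roi` (logical rows x cols lung mask).
#' @slot phaseLabels factor of length n-frames with levels
#'   `air1`, `O2`, `air2`, shared by all sections.
#' @slot sectionLocations character, one identifier per section
#'   (e.g. "anterior", "central", "posterior").
#' @slot phaseDurations numeric(3), nominal phase durations in minutes.
#'
#' @seealso [selectPhaseWindows()], [rerAnalysis()]
#' @export
setClass("OEMRISeries",
  representation(
    sections = "list",
    phaseLabels = "factor",
    sectionLocations = "character",
    phaseDurations = "numeric"
  ),
  prototype(phaseDurations = c(5, 5, 5))
)

setValidity("OEMRISeries", function(object) {
  msg <- character()
  if (length(object@sections) < 1L)
    msg <- c(msg, "at least one section required")
  if (!identical(levels(object@phaseLabels), c("air1", "O2", "air2")))
    msg <- c(msg, "phaseLabels must have levels air1, O2, air2")
  if (any(is.na(object@phaseLabels)))
    msg <- c(msg, "every frame must have a phase label")
  if (!all(c("air1", "O2", "air2") %in% as.character(object@phaseLabels)))
    msg <- c(msg, "each phase must be non-empty")
  nf <- length(object@phaseLabels)
  for (i in seq_along(object@sections)) {
    s <- object@sections[[i]]
    if (!all(c("frames", "spacing", "zcoord", "roi") %in% names(s))) {
      msg <- c(msg, sprintf("section %d missing components", i))
      next
    }
    d <- dim(s$frames)
    if (length(d) != 3L || d[3] != nf)
      msg <- c(msg, sprintf("section %d: frame count must equal phase-label count", i))
    if (!identical(dim(s$roi), d[1:2]))
      msg <- c(msg, sprintf("section %d: ROI must be congruent with frames", i))
    if (length(s$zcoord) != d[1])
      msg <- c(msg, sprintf("section %d: zcoord must map every pixel row", i))
  }
  if (length(object@sectionLocations) != length(object@sections))
    msg <- c(msg, "one location identifier per section required")
  if (length(msg)) msg else TRUE
})

#' PartitionScheme: isovolumetric cranial-caudal lung partition assignment
#'
#' Lung voxels ordered cranial to caudal are split into `nTotal` partitions
#' of equal voxel count (equal volume under uniform spacing). The remainder
#' of an inexact division goes to the earliest partitions, and in-slice
#' order is row-major, so the assignment is deterministic. By default the
#' top and bottom partitions are excluded from heterogeneity summaries
#' because of the partial volume effect at the lung apices and bases.
#'
#' @slot nTotal integer, number of partitions before exclusion (default 12).
#' @slot kept integer vector of retained partition indices (default 2:11).
#' @slot assignment integer vector, partition index of each lung voxel in
#'   the canonical (slice-major, in-slice row-major) order.
#' @slot counts integer(nTotal), voxels per partition.
#' @slot voxelIndex integer vector, linear array index of each lung voxel
#'   in the same order as `assignment`.
#'
#' @export
setClass("PartitionScheme",
  representation(
    nTotal = "integer",
    kept = "integer",
    assignment = "integer",
    counts = "integer",
    voxelIndex = "integer"
  )
)

setValidity("PartitionScheme", function(object) {
  msg <- character()
  if (object@nTotal < 1L) msg <- c(msg, "nTotal must be positive")
  if (length(object@assignment) != length(object@voxelIndex))
    msg <- c(msg, "assignment and voxelIndex must be parallel")
  if (!all(object@kept %in% seq_len(object@nTotal)))
    msg <- c(msg, "kept indices must lie in 1..nTotal")
  tab <- tabulate(object@assignment, nbins = object@nTotal)
  if (!identical(as.integer(tab), object@counts))
    msg <- c(msg, "counts must recount the assignment")
  if (any(tab == 0L))
    msg <- c(msg, "every partition must contain at least one voxel")
  if (length(msg)) msg else TRUE
})

#' LavResult: low attenuation volume densitometry summary
#'
#' @slot lavPercentWhole numeric, whole-lung LAV% (percentage of all lung
#'   voxels below the threshold, end partitions included).
#' @slot perPartition numeric, LAV% of each kept partition (default 10).
#' @slot sdLav numeric, sample standard deviation (n-1 denominator) of the
#'   kept per-partition LAV% values; the cranial-caudal heterogeneity index.
#' @slot threshold numeric, HU cut-off (default -960; strict `<`).
#' @slot calibrationShift numeric, additive HU shift applied before
#'   thresholding.
#' @slot partitionCounts integer, voxel count of every partition (all
#'   `nTotal`, not only kept).
#' @slot keptIndices integer, which partitions entered `sdLav`.
#'
#' @export
setClass("LavResult",
  representation(
    lavPercentWhole = "numeric",
    perPartition = "numeric",
    sdLav = "numeric",
    threshold = "numeric",
    calibrationShift = "numeric",
    partitionCounts = "integer",
    keptIndices = "integer"
  )
)

setValidity("LavResult", function(object) {
  msg <- character()
  vals <- c(object@lavPercentWhole, object@perPartition)
  if (any(vals < 0 | vals > 100)) msg <- c(msg, "LAV% values must lie in [0, 100]")
  if (object@sdLav < 0) msg <- c(msg, "sdLav must be non-negative")
  if (length(msg)) msg else TRUE
})

#' RerResult: relative enhancement ratio summary over an OEMRI exam
#'
#' @slot rerMaps list of per-section numeric matrices, RER in percent per
#'   ROI pixel (NA outside the ROI or where the baseline floor excluded a
#'   pixel).
#' @slot mrer numeric, mean RER over the pooled lung-ROI pixels of all
#'   sections (pixel-weighted).
#' @slot perPartition numeric, mean RER of each cranial-caudal partition
#'   (default 10, no end exclusion).
#' @slot sdRer numeric, sample SD of the per-partition means; the
#'   oxygen-uptake heterogeneity index.
#' @slot baselineWindow integer, frame indices averaged for SI_baseline.
#' @slot enhancedWindow integer, frame indices averaged for SI_enhanced.
#' @slot excludedPixels integer, ROI pixels dropped by the low-baseline
#'   floor.
#'
#' @export
setClass("RerResult",
  representation(
    rerMaps = "list",
    mrer = "numeric",
    perPartition = "numeric",
    sdRer = "numeric",
    baselineWindow = "integer",
    enhancedWindow = "integer",
    excludedPixels = "integer"
  )
)

setValidity("RerResult", function(object) {
  msg <- character()
  if (any(object@perPartition < 0) || any(unlist(object@rerMaps) < 0, na.rm = TRUE))
    msg <- c(msg, "RER values must be non-negative (absolute-value formula)")
  if (object@sdRer < 0) msg <- c(msg, "sdRer must be non-negative")
  if (length(object@perPartition) &&
      (object@mrer < min(object@perPartition) - 1e-9 ||
       object@mrer > max(object@perPartition) + 1e-9))
    msg <- c(msg, "mrer must lie between the per-partition extremes")
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: ground truth recorded by the synthetic generators
#'
#' Everything the phantom generator knows and the measurement pipeline must
#' recover: the per-voxel emphysema label, the realized low-attenuation
#' fractions, the per-pixel oxygen-enhancement amplitude, and (for cohorts)
#' the noiseless covariate means.
#'
#' @slot emphysemaLabel logical array, TRUE where a voxel was generated as
#'   emphysema (congruent with the phantom's `hu`).
#' @slot lavFractionWhole numeric, realized whole-lung emphysema fraction.
#' @slot lavFractionPerPartition numeric, realized per-partition fractions
#'   under the default 12-partition scheme.
#' @slot amplitudeTrue list of per-section numeric matrices of the true
#'   enhancement amplitude (empty until an OEMRI phantom is generated).
#' @slot covariateMeans list, per-subject noiseless covariate values
#'   (cohort use only).
#'
#' @export
setClass("PhantomTruth",
  representation(
    emphysemaLabel = "array",
    lavFractionWhole = "numeric",
    lavFractionPerPartition = "numeric",
    amplitudeTrue = "list",
    covariateMeans = "list"
  ),
  prototype(amplitudeTrue = list(), covariateMeans = list())
)
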