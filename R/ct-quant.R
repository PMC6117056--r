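#' Calibrate HU values against tracheal air
#'
#' Clinical densitometry adjusts CT numbers so that tracheal air reads
#' exactly -1000 HU, removing scanner-to-scanner offset before any
#' threshold is applied. The adjustment is a single additive shift: the
#' minimal model that preserves threshold semantics (a constant offset in
#' the acquisition moves every voxel equally).
#'
#' @param volume a [CTVolume-class] with a non-empty trachea mask.
#' @return a [CTVolume-class] whose tracheal mean HU is -1000; the applied
#'   shift is recorded in `calibrationShift()` (cumulative if calibrated
#'   twice).
#' @examples
#' ph <- generateCTPhantom(ctPhantomConfig(globalHUOffset = 15, seed = 2))
#' cal <- calibrateHU(ph$volume)
#' calibrationShift(cal)  # about -15
#' @export
calibrateHU <- function(volume) {
  stopifnot(is(volume, "CTVolume"))
  if (!any(volume@tracheaMask)) stop("trachea mask is empty; cannot calibrate")
  shift <- -1000 - mean(volume@hu[volume@tracheaMask])
  if (abs(shift) > 100)
    warning(sprintf(
      "calibration shift %.1f HU exceeds 100 HU; trachea mask is suspect",
      shift))
  methods::new("CTVolume", hu = volume@hu + shift, spacing = volume@spacing,
               lungMask = volume@lungMask, tracheaMask = volume@tracheaMask,
               calibrationShift = volume@calibrationShift + shift)
}

#' Low attenuation volume mask
#'
#' Marks lung voxels strictly below the emphysema threshold. The cut-off
#' is strict (`<`), and voxels outside the lung mask are never counted,
#' whatever their HU.
#'
#' @param volume a calibrated [CTVolume-class].
#' @param threshold HU cut-off, default -960.
#' @return logical array, TRUE where `lungMask & hu < threshold`.
#' @export
lavMask <- function(volume, threshold = -960) {
  stopifnot(is(volume, "CTVolume"))
  volume@lungMask & (volume@hu < threshold)
}

#' Isovolumetric cranial-caudal lung partitioning
#'
#' Orders the lung voxels from the cranial to the caudal end (slice-major;
#' row-major within a slice) and cuts the sequence into `n` partitions of
#' equal voxel count. When the count does not divide exactly, the
#' remainder goes to the earliest partitions, so voxels of a boundary
#' slice fill the earlier partition until its quota is met and spill into
#' the next — the assignment is fully deterministic. With
#' `excludeEnds = TRUE` (the default) the first and last partitions are
#' dropped from heterogeneity summaries, compensating the partial volume
#' effect at the apices and bases.
#'
#' @param volume a [CTVolume-class].
#' @param n number of partitions before exclusion (default 12).
#' @param excludeEnds drop the first and last partition from the kept set.
#' @return a [PartitionScheme-class].
#' @export
partitionIsovolumetric <- function(volume, n = 12L, excludeEnds = TRUE) {
  stopifnot(is(volume, "CTVolume"))
  n <- as.integer(n)
  if (excludeEnds && n < 3L) stop("n < 3 with end exclusion keeps nothing")
  idx <- orderedLungVoxels(volume@lungMask)
  if (length(idx) < n)
    stop(sprintf("only %d lung voxels for %d partitions", length(idx), n))
  quotas <- partitionQuotas(length(idx), n)
  assignment <- rep.int(seq_len(n), times = quotas)
  kept <- if (excludeEnds) seq_len(n)[-c(1L, n)] else seq_len(n)
  methods::new("PartitionScheme", nTotal = n, kept = as.integer(kept),
               assignment = as.integer(assignment), counts = quotas,
               voxelIndex = idx)
}

#' Per-partition LAV percentages
#'
#' @param mask logical LAV array from [lavMask()].
#' @param scheme a [PartitionScheme-class] from the same volume.
#' @param keptOnly return only the kept partitions (default) or all.
#' @return numeric vector of per-partition LAV% (100 x LAV voxels in the
#'   partition / partition voxel count).
#' @export
lavPercentPerPartition <- function(mask, scheme, keptOnly = TRUE) {
  stopifnot(is(scheme, "PartitionScheme"))
  lavHits <- mask[scheme@voxelIndex]
  counts <- vapply(seq_len(scheme@nTotal), function(p)
    sum(lavHits[scheme@assignment == p]), numeric(1))
  pct <- 100 * counts / scheme@counts
  if (keptOnly) pct[scheme@kept] else pct
}

#' Cranial-caudal heterogeneity index from per-partition values
#'
#' The standard deviation of the per-partition LAV% (or RER) values; a
#' higher value means a more heterogeneous cranial-caudal distribution.
#' The sample (n-1) denominator is the default; the population convention
#' is available since the field literature rarely states which is meant.
#'
#' @param values numeric, per-partition percentages.
#' @param denominator `"sample"` (n-1, default) or `"population"` (n).
#' @return the SD in the same units as `values`.
#' @export
partitionSD <- function(values, denominator = c("sample", "population")) {
  sampleSD(values, match.arg(denominator))
}

#' Full CT densitometry: whole-lung LAV%, per-partition LAV%, SD-LAV
#'
#' Runs the complete densitometry chain on a volume: tracheal-air HU
#' calibration (optional if already calibrated), strict thresholding,
#' 12-partition isovolumetric cranial-caudal partitioning, per-partition
#' LAV%, and the SD-LAV heterogeneity index over the 10 kept partitions.
#' The whole-lung LAV% is computed over the entire lung mask — end
#' partitions included; only the SD uses the kept set.
#'
#' @param volume a [CTVolume-class].
#' @param threshold HU cut-off (default -960, strict `<`).
#' @param nPartitions partitions before end exclusion (default 12).
#' @param calibrate run [calibrateHU()] first (default TRUE).
#' @param excludeEnds exclude the top and bottom partitions from SD-LAV.
#' @param denominator SD convention, see [partitionSD()].
#' @return a [LavResult-class].
#' @examples
#' ph <- generateCTPhantom(ctPhantomConfig(lavFractionTarget = 0.3,
#'                                         parenchymaHUSD = 0,
#'                                         emphysemaHUSD = 0, seed = 11))
#' res <- ctDensitometry(ph$volume)
#' lavPercent(res)  # about 30
#' @export
ctDensitometry <- function(volume, threshold = -960, nPartitions = 12L,
                           calibrate = TRUE, excludeEnds = TRUE,
                           denominator = c("sample", "population")) {
  stopifnot(is(volume, "CTVolume"))
  if (calibrate) volume <- calibrateHU(volume)
  mask <- lavMask(volume, threshold)
  scheme <- partitionIsovolumetric(volume, nPartitions, excludeEnds)
  allPct <- lavPercentPerPartition(mask, scheme, keptOnly = FALSE)
  keptPct <- allPct[scheme@kept]
  methods::new("LavResult",
    lavPercentWhole = 100 * sum(mask & volume@lungMask) / sum(volume@lungMask),
    perPartition = keptPct,
    sdLav = partitionSD(keptPct, match.arg(denominator)),
    threshold = threshold,
    calibrationShift = volume@calibrationShift,
    partitionCounts = scheme@counts,
    keptIndices = scheme@kept)
}
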