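#' Select baseline and oxygen-enhanced frame windows
#'
#' The acquisition never states which single frames represent the baseline
#' and enhanced conditions, so the steady-state tails of the room-air and
#' oxygen phases are averaged: the last `ceiling(windowFraction * n)`
#' frames of `air1` form the baseline window and the last
#' `ceiling(windowFraction * n)` frames of `O2` the enhanced window. The
#' default fraction 0.5 skips the wash-in transient.
#'
#' @param series an [OEMRISeries-class].
#' @param windowFraction fraction of each phase kept, in `(0, 1]`.
#' @return list with integer frame-index vectors `baseline` and
#'   `enhanced`.
#' @export
selectPhaseWindows <- function(series, windowFraction = 0.5) {
  stopifnot(is(series, "OEMRISeries"))
  if (windowFraction <= 0 || windowFraction > 1)
    stop("windowFraction must lie in (0, 1]")
  lab <- series@phaseLabels
  pick <- function(phase) {
    idx <- which(lab == phase)
    if (!length(idx)) stop(sprintf("phase %s is empty", phase))
    k <- ceiling(windowFraction * length(idx))
    utils::tail(idx, k)
  }
  list(baseline = pick("air1"), enhanced = pick("O2"))
}

#' Per-pixel relative enhancement ratio map
#'
#' Computes `RER = 100 * |SI_enhanced - SI_baseline| / |SI_baseline|` per
#' ROI pixel. The absolute value makes signal drops positive too, so every
#' RER is non-negative. Pixels whose baseline magnitude falls below
#' `floor` are excluded from the ROI (division blow-up guard) and counted.
#'
#' @param baselineMean numeric matrix, window-averaged baseline image.
#' @param enhancedMean numeric matrix, window-averaged enhanced image.
#' @param roi logical matrix, lung region of interest.
#' @param floor positive signal level below which a baseline pixel is
#'   excluded.
#' @return list with `map` (RER percent matrix, NA outside the effective
#'   ROI) and `excluded` (count of floor-excluded ROI pixels).
#' @export
rerMap <- function(baselineMean, enhancedMean, roi, floor) {
  stopifnot(identical(dim(baselineMean), dim(enhancedMean)),
            identical(dim(baselineMean), dim(roi)))
  if (floor <= 0) stop("floor must be positive")
  ok <- roi & abs(baselineMean) >= floor
  excluded <- sum(roi) - sum(ok)
  if (!any(ok)) stop("all ROI pixels fall below the baseline floor")
  map <- matrix(NA_real_, nrow(roi), ncol(roi))
  map[ok] <- 100 * abs(enhancedMean[ok] - baselineMean[ok]) /
    abs(baselineMean[ok])
  list(map = map, excluded = as.integer(excluded))
}

#' Mean relative enhancement ratio over pooled sections
#'
#' The whole-lung oxygen-uptake index: the unweighted mean over all pooled
#' ROI pixels of all sections, so a larger section contributes in
#' proportion to its pixel count.
#'
#' @param maps list of RER matrices (NA outside the effective ROI).
#' @return MRER in percent.
#' @export
meanRER <- function(maps) {
  vals <- unlist(lapply(maps, function(m) m[!is.na(m)]))
  if (!length(vals)) stop("empty pooled ROI")
  mean(vals)
}

#' Cranial-caudal SD of partition-mean RER (SD-RER)
#'
#' Pools the effective-ROI pixels of all sections, orders them by their
#' physical cranial-caudal coordinate, splits them into `n` equal-count
#' partitions (remainder to the earliest partitions, ties in coordinate
#' broken by section then in-section order), and returns the sample SD of
#' the `n` partition means. Unlike the CT scheme there is no end
#' exclusion: the protocol summarizes 10 direct parts. Set
#' `excludeEnds = TRUE` to mimic the CT 12-minus-2 scheme for sensitivity
#' analysis.
#'
#' @param maps list of per-section RER matrices.
#' @param zcoords list of per-section row-coordinate vectors (mm,
#'   increasing caudal).
#' @param n partitions (default 10).
#' @param excludeEnds drop first and last partition from the SD.
#' @param denominator SD convention, see [partitionSD()].
#' @return list with `sd` (SD-RER, percent) and `perPartition` (the kept
#'   partition means).
#' @export
sdRERPartitioned <- function(maps, zcoords, n = 10L, excludeEnds = FALSE,
                             denominator = c("sample", "population")) {
  n <- as.integer(n)
  vals <- list(); zs <- list(); ord <- list()
  for (s in seq_along(maps)) {
    m <- maps[[s]]
    keep <- which(!is.na(m), arr.ind = TRUE)
    if (!nrow(keep)) next
    vals[[s]] <- m[keep]
    zs[[s]] <- zcoords[[s]][keep[, 1]]
    ord[[s]] <- rep(s, nrow(keep))
  }
  v <- unlist(vals); z <- unlist(zs); sec <- unlist(ord)
  if (length(v) < n)
    stop(sprintf("only %d pooled ROI pixels for %d partitions", length(v), n))
  o <- order(z, sec)  # stable: ties by section, then in-section order
  v <- v[o]
  assignment <- rep.int(seq_len(n), times = partitionQuotas(length(v), n))
  means <- vapply(seq_len(n), function(p) mean(v[assignment == p]), numeric(1))
  kept <- if (excludeEnds) means[-c(1L, n)] else means
  list(sd = partitionSD(kept, match.arg(denominator)), perPartition = kept)
}

#' Full OEMRI quantification: RER maps, MRER, SD-RER
#'
#' Runs the complete oxygen-enhanced MRI chain: steady-state phase-window
#' selection, window averaging, per-pixel RER with a low-baseline floor,
#' pixel-weighted MRER over all sections, and the 10-partition
#' cranial-caudal SD-RER.
#'
#' @param series an [OEMRISeries-class].
#' @param windowFraction fraction of each phase averaged (default 0.5).
#' @param nPartitions cranial-caudal partitions for SD-RER (default 10).
#' @param floorFraction the low-baseline floor as a fraction of the median
#'   ROI baseline signal (default 0.05).
#' @param excludeEnds mimic the CT end-exclusion scheme (default FALSE).
#' @param denominator SD convention, see [partitionSD()].
#' @return a [RerResult-class].
#' @examples
#' ph <- generateOEMRIPhantom(oemriPhantomConfig(noiseSD = 0))
#' res <- rerAnalysis(ph$series)
#' mrer(res)  # about 22
#' @export
rerAnalysis <- function(series, windowFraction = 0.5, nPartitions = 10L,
                        floorFraction = 0.05, excludeEnds = FALSE,
                        denominator = c("sample", "population")) {
  stopifnot(is(series, "OEMRISeries"))
  win <- selectPhaseWindows(series, windowFraction)
  maps <- list(); zcoords <- list(); excluded <- 0L
  for (s in seq_along(series@sections)) {
    sec <- series@sections[[s]]
    base <- apply(sec$frames[, , win$baseline, drop = FALSE], c(1, 2), mean)
    enh <- apply(sec$frames[, , win$enhanced, drop = FALSE], c(1, 2), mean)
    floor <- floorFraction * stats::median(base[sec$roi])
    if (!is.finite(floor) || floor <= 0)
      floor <- .Machine$double.eps
    rm <- rerMap(base, enh, sec$roi, floor)
    maps[[s]] <- rm$map
    zcoords[[s]] <- sec$zcoord
    excluded <- excluded + rm$excluded
  }
  sdr <- sdRERPartitioned(maps, zcoords, nPartitions, excludeEnds,
                          denominator)
  methods::new("RerResult", rerMaps = maps, mrer = meanRER(maps),
               perPartition = sdr$perPartition, sdRer = sdr$sd,
               baselineWindow = as.integer(win$baseline),
               enhancedWindow = as.integer(win$enhanced),
               excludedPixels = as.integer(excluded))
}
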