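#' @include AllClasses.R
NULL

#' Accessors for imaging objects and result summaries
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param object a `CTVolume`, `OEMRISeries`, `PartitionScheme`,
#'   `LavResult`, `RerResult`, or `PhantomTruth`.
#' @return The corresponding component; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("huArray", function(object) standardGeneric("huArray"))
#' @rdname accessors
#' @export
setMethod("huArray", "CTVolume", function(object) object@hu)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CTVolume", function(object) object@spacing)

#' @rdname accessors
#' @export
setGeneric("lungMask", function(object) standardGeneric("lungMask"))
#' @rdname accessors
#' @export
setMethod("lungMask", "CTVolume", function(object) object@lungMask)

#' @rdname accessors
#' @export
setGeneric("tracheaMask", function(object) standardGeneric("tracheaMask"))
#' @rdname accessors
#' @export
setMethod("tracheaMask", "CTVolume", function(object) object@tracheaMask)

#' @rdname accessors
#' @export
setGeneric("calibrationShift", function(object) standardGeneric("calibrationShift"))
#' @rdname accessors
#' @export
setMethod("calibrationShift", "CTVolume", function(object) object@calibrationShift)
#' @rdname accessors
#' @export
setMethod("calibrationShift", "LavResult", function(object) object@calibrationShift)

#' @rdname accessors
#' @export
setGeneric("sections", function(object) standardGeneric("sections"))
#' @rdname accessors
#' @export
setMethod("sections", "OEMRISeries", function(object) object@sections)

#' @rdname accessors
#' @export
setGeneric("phaseLabels", function(object) standardGeneric("phaseLabels"))
#' @rdname accessors
#' @export
setMethod("phaseLabels", "OEMRISeries", function(object) object@phaseLabels)

#' @rdname accessors
#' @export
setGeneric("partitionCounts", function(object) standardGeneric("partitionCounts"))
#' @rdname accessors
#' @export
setMethod("partitionCounts", "PartitionScheme", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("partitionCounts", "LavResult", function(object) object@partitionCounts)

#' @rdname accessors
#' @export
setGeneric("keptPartitions", function(object) standardGeneric("keptPartitions"))
#' @rdname accessors
#' @export
setMethod("keptPartitions", "PartitionScheme", function(object) object@kept)
#' @rdname accessors
#' @export
setMethod("keptPartitions", "LavResult", function(object) object@keptIndices)

#' @rdname accessors
#' @export
setGeneric("lavPercent", function(object) standardGeneric("lavPercent"))
#' @rdname accessors
#' @export
setMethod("lavPercent", "LavResult", function(object) object@lavPercentWhole)

#' @rdname accessors
#' @export
setGeneric("perPartition", function(object) standardGeneric("perPartition"))
#' @rdname accessors
#' @export
setMethod("perPartition", "LavResult", function(object) object@perPartition)
#' @rdname accessors
#' @export
setMethod("perPartition", "RerResult", function(object) object@perPartition)

#' @rdname accessors
#' @export
setGeneric("sdLav", function(object) standardGeneric("sdLav"))
#' @rdname accessors
#' @export
setMethod("sdLav", "LavResult", function(object) object@sdLav)

#' @rdname accessors
#' @export
setGeneric("mrer", function(object) standardGeneric("mrer"))
#' @rdname accessors
#' @export
setMethod("mrer", "RerResult", function(object) object@mrer)

#' @rdname accessors
#' @export
setGeneric("sdRer", function(object) standardGeneric("sdRer"))
#' @rdname accessors
#' @export
setMethod("sdRer", "RerResult", function(object) object@sdRer)

#' @rdname accessors
#' @export
setGeneric("rerMaps", function(object) standardGeneric("rerMaps"))
#' @rdname accessors
#' @export
setMethod("rerMaps", "RerResult", function(object) object@rerMaps)

#' @rdname accessors
#' @export
setGeneric("emphysemaLabel", function(object) standardGeneric("emphysemaLabel"))
#' @rdname accessors
#' @export
setMethod("emphysemaLabel", "PhantomTruth", function(object) object@emphysemaLabel)

#' @rdname accessors
#' @export
setGeneric("trueLavFraction", function(object) standardGeneric("trueLavFraction"))
#' @rdname accessors
#' @export
setMethod("trueLavFraction", "PhantomTruth", function(object) object@lavFractionWhole)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@hu)
  cat("CTVolume:", paste(d, collapse = " x "), "voxels,",
      paste(format(object@spacing, digits = 3), collapse = " x "), "mm\n")
  cat("  lung voxels:", sum(object@lungMask),
      " trachea voxels:", sum(object@tracheaMask), "\n")
  cat("  calibration shift applied:",
      format(object@calibrationShift, digits = 4), "HU\n")
})

setMethod("show", "OEMRISeries", function(object) {
  cat("OEMRISeries:", length(object@sections), "section(s) [",
      paste(object@sectionLocations, collapse = ", "), "]\n")
  cat("  frames:", length(object@phaseLabels), "(",
      paste(sprintf("%s=%d", levels(object@phaseLabels),
                    tabulate(object@phaseLabels)), collapse = ", "), ")\n")
})

setMethod("show", "PartitionScheme", function(object) {
  cat("PartitionScheme:", object@nTotal, "isovolumetric partitions,",
      length(object@kept), "kept (",
      paste(range(object@kept), collapse = "-"), ")\n")
  cat("  per-partition voxel counts:",
      paste(object@counts, collapse = " "), "\n")
})

setMethod("show", "LavResult", function(object) {
  cat("LavResult (threshold", object@threshold, "HU, shift",
      format(object@calibrationShift, digits = 4), "HU)\n")
  cat("  whole-lung LAV%:", format(object@lavPercentWhole, digits = 4), "\n")
  cat("  SD-LAV over", length(object@perPartition), "partitions:",
      format(object@sdLav, digits = 4), "\n")
})

setMethod("show", "RerResult", function(object) {
  cat("RerResult over", length(object@rerMaps), "section(s)\n")
  cat("  MRER:", format(object@mrer, digits = 4),
      "%  SD-RER:", format(object@sdRer, digits = 4), "%\n")
  cat("  excluded low-baseline pixels:", object@excludedPixels, "\n")
})
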