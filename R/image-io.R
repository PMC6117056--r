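## On-disk model: NIfTI for volumes and frame stacks (spacing carried in
## pixdim, cranial slice first), companion mask files alongside the HU
## volume, JSON sidecars for per-series metadata, CSV for tables, YAML for
## run configs.

# uncompressed .nii so that re-runs are byte-identical (gzip embeds
# timestamps) and round-trips are trivially lossless
niftiPath <- function(stem, suffix = "")
  paste0(stem, if (nzchar(suffix)) paste0("_", suffix), ".nii")

writeNiftiArray <- function(arr, path, spacing) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  # canonical orientation: slice index grows toward the feet, so the
  # z-axis direction cosine is negative (RAS convention)
  aff <- diag(c(spacing[1], spacing[2], -spacing[3], 1))
  attr(aff, "code") <- 2L
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a CTVolume as NIfTI with companion mask files
#'
#' The HU volume goes to `<stem>.nii.gz`, the masks to
#' `<stem>_lung.nii.gz` and `<stem>_trachea.nii.gz` (stored as 0/1
#' volumes). Voxel spacing is carried in the NIfTI pixdim; slice index 1
#' is cranial by convention, enforced at read time: a file whose z-axis
#' direction (xform third column) points cranially is flipped on load and
#' the flip is reported via a message. Round-trips preserve voxel values
#' exactly and spacing to float precision.
#'
#' @param volume a [CTVolume-class].
#' @param stem path stem without extension.
#' @return `writeCTVolume`: the stem, invisibly. `readCTVolume`: a
#'   [CTVolume-class].
#' @export
writeCTVolume <- function(volume, stem) {
  stopifnot(is(volume, "CTVolume"))
  writeNiftiArray(volume@hu, niftiPath(stem), volume@spacing)
  writeNiftiArray(volume@lungMask * 1, niftiPath(stem, "lung"),
                  volume@spacing)
  writeNiftiArray(volume@tracheaMask * 1, niftiPath(stem, "trachea"),
                  volume@spacing)
  invisible(stem)
}

#' @rdname writeCTVolume
#' @export
readCTVolume <- function(stem) {
  main <- niftiPath(stem)
  if (!file.exists(main)) stop("volume file not found: ", main)
  lungFile <- niftiPath(stem, "lung")
  if (!file.exists(lungFile))
    stop("lung mask required but not found: ", lungFile)
  tracheaFile <- niftiPath(stem, "trachea")
  if (!file.exists(tracheaFile))
    stop("trachea mask required but not found: ", tracheaFile)
  img <- RNifti::readNifti(main)
  spacing <- RNifti::pixdim(img)[1:3]
  hu <- array(as.numeric(img), dim = dim(img))
  lung <- array(as.numeric(RNifti::readNifti(lungFile)) > 0.5, dim = dim(img))
  trachea <- array(as.numeric(RNifti::readNifti(tracheaFile)) > 0.5,
                   dim = dim(img))
  # canonical axis convention: slice index 1 cranial (z grows caudal);
  # a file stored with z increasing toward the head is reoriented here
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (!inherits(xf, "try-error") && is.matrix(xf) && xf[3, 3] > 0) {
    flip <- function(a) a[, , rev(seq_len(dim(a)[3])), drop = FALSE]
    hu <- flip(hu); lung <- flip(lung); trachea <- flip(trachea)
    message("reoriented volume: flipped slice axis so index 1 is cranial")
  }
  methods::new("CTVolume", hu = hu, spacing = as.numeric(spacing),
               lungMask = lung, tracheaMask = trachea, calibrationShift = 0)
}

#' Write / read an OEMRISeries
#'
#' Each section's frame stack is written as a 3-D NIfTI (frame axis last)
#' at `<stem>_sec<i>.nii.gz` with its ROI at `<stem>_sec<i>_roi.nii.gz`;
#' phase labels, phase durations, section locations, spacings and
#' cranial-caudal row coordinates go to the JSON sidecar `<stem>.json`.
#'
#' @param series an [OEMRISeries-class].
#' @param stem path stem without extension.
#' @return `writeOEMRISeries`: the stem, invisibly. `readOEMRISeries`: an
#'   [OEMRISeries-class].
#' @export
writeOEMRISeries <- function(series, stem) {
  stopifnot(is(series, "OEMRISeries"))
  meta <- list(
    phaseLabels = as.character(series@phaseLabels),
    phaseDurations = series@phaseDurations,
    sectionLocations = series@sectionLocations,
    sections = lapply(series@sections, function(s)
      list(spacing = s$spacing, zcoord = s$zcoord))
  )
  jsonWrite(meta, paste0(stem, ".json"))
  for (i in seq_along(series@sections)) {
    s <- series@sections[[i]]
    writeNiftiArray(s$frames, niftiPath(stem, sprintf("sec%d", i)),
                    c(s$spacing, 1))
    writeNiftiArray(s$roi * 1, niftiPath(stem, sprintf("sec%d_roi", i)),
                    c(s$spacing, 1))
  }
  invisible(stem)
}

#' @rdname writeOEMRISeries
#' @export
readOEMRISeries <- function(stem) {
  metaFile <- paste0(stem, ".json")
  if (!file.exists(metaFile)) stop("series metadata not found: ", metaFile)
  meta <- jsonlite::read_json(metaFile, simplifyVector = TRUE)
  labels <- factor(meta$phaseLabels, levels = c("air1", "O2", "air2"))
  secMeta <- meta$sections
  nSec <- if (is.data.frame(secMeta)) nrow(secMeta) else length(secMeta)
  sectionsList <- lapply(seq_len(nSec), function(i) {
    frames <- RNifti::readNifti(niftiPath(stem, sprintf("sec%d", i)))
    roi <- RNifti::readNifti(niftiPath(stem, sprintf("sec%d_roi", i)))
    frames <- array(as.numeric(frames), dim = dim(frames))
    if (dim(frames)[3] != length(labels))
      stop(sprintf("section %d: frame count %d != %d phase labels",
                   i, dim(frames)[3], length(labels)))
    sm <- if (is.data.frame(secMeta)) lapply(secMeta, `[[`, i) else secMeta[[i]]
    list(frames = frames,
         spacing = as.numeric(unlist(sm$spacing)),
         zcoord = as.numeric(unlist(sm$zcoord)),
         roi = array(as.numeric(roi) > 0.5, dim = dim(roi)[1:2]))
  })
  methods::new("OEMRISeries", sections = sectionsList, phaseLabels = labels,
               sectionLocations = as.character(meta$sectionLocations),
               phaseDurations = as.numeric(meta$phaseDurations))
}

cohortSchema <- c("id", "group", "age", "bmi", "fev1_l", "pct_fev1",
                  "fvc_l", "vc_l", "rv_tlc", "dlco", "pao2", "paco2",
                  "lav_pct", "sd_lav", "mrer", "sd_rer")

#' Write / read a cohort covariate table as CSV
#'
#' The schema is the study's per-subject variable set: `id`, `group`
#' (COPD/control), demographics, pulmonary function (FEV1 in L, %FEV1,
#' FVC, VC, RV/TLC in %, DL_CO in mL/min/mmHg), arterial blood gases
#' (PaO2, PaCO2 in Torr), and the imaging indices (LAV%, SD-LAV, MRER,
#' SD-RER, all percent). Unknown columns are carried through with a
#' warning; duplicate ids or invalid group labels are errors. Numeric
#' values survive the round-trip to 15 significant digits.
#'
#' @param table a cohort data.frame.
#' @param path CSV file path.
#' @return `writeCohortTable`: the path, invisibly. `readCohortTable`:
#'   the validated data.frame.
#' @export
writeCohortTable <- function(table, path) {
  validateCohortTable(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortTable
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateCohortTable(tab)
  tab
}

validateCohortTable <- function(tab) {
  missing <- setdiff(c("id", "group"), names(tab))
  if (length(missing))
    stop("cohort table missing required columns: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(tab), cohortSchema)
  if (length(extra))
    warning("unknown cohort columns carried through untouched: ",
            paste(extra, collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("duplicate subject ids in cohort table")
  if (!all(tab$group %in% c("COPD", "control")))
    stop("group labels must be 'COPD' or 'control'")
  invisible(tab)
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file with optional blocks `cohort`, `ct`, `oemri`,
#'   `pipeline` whose keys override the corresponding config defaults.
#' @return nested list of configuration values.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path)
}
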