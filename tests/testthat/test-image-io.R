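test_that("CT volume round-trips exactly, including anisotropic spacing", {
  ph <- generateCTPhantom(ctPhantomConfig(
    voxelSpacing = c(0.7, 0.7, 0.5), clusterRadiusMM = 0.8,
    lavFractionTarget = 0.1, seed = 3))
  stem <- file.path(withr::local_tempdir(), "vol")
  writeCTVolume(ph$volume, stem)
  v2 <- readCTVolume(stem)
  expect_identical(huArray(v2), huArray(ph$volume))
  expect_identical(lungMask(v2), lungMask(ph$volume))
  expect_identical(tracheaMask(v2), tracheaMask(ph$volume))
  expect_equal(voxelSpacing(v2), c(0.7, 0.7, 0.5), tolerance = 1e-6)
})

test_that("missing companion masks raise named errors", {
  ph <- generateCTPhantom(ctPhantomConfig(seed = 2))
  dir <- withr::local_tempdir()
  stem <- file.path(dir, "vol")
  writeCTVolume(ph$volume, stem)
  file.remove(paste0(stem, "_lung.nii"))
  expect_error(readCTVolume(stem), "lung mask required")
  expect_error(readCTVolume(file.path(dir, "nothere")), "not found")
})

test_that("a head-first stored volume is reoriented so slice 1 is cranial", {
  ph <- generateCTPhantom(ctPhantomConfig(seed = 4))
  dir <- withr::local_tempdir()
  sp <- voxelSpacing(ph$volume)
  writeFlipped <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- sp
    aff <- diag(c(sp[1], sp[2], sp[3], 1))  # positive z: head-first
    attr(aff, "code") <- 2L
    RNifti::qform(img) <- aff
    RNifti::writeNifti(img, path)
  }
  writeFlipped(huArray(ph$volume), file.path(dir, "f.nii"))
  writeFlipped(lungMask(ph$volume) * 1, file.path(dir, "f_lung.nii"))
  writeFlipped(tracheaMask(ph$volume) * 1, file.path(dir, "f_trachea.nii"))
  expect_message(v <- readCTVolume(file.path(dir, "f")), "reoriented")
  nz <- dim(huArray(ph$volume))[3]
  expect_identical(huArray(v), huArray(ph$volume)[, , rev(seq_len(nz))])
})

test_that("OEMRI series round-trips frames, labels, ROI and coordinates", {
  ph <- generateOEMRIPhantom(oemriPhantomConfig(framesPerPhase = 6, seed = 4))
  stem <- file.path(withr::local_tempdir(), "ser")
  writeOEMRISeries(ph$series, stem)
  s2 <- readOEMRISeries(stem)
  expect_identical(phaseLabels(s2), phaseLabels(ph$series))
  for (i in 1:3) {
    expect_identical(sections(s2)[[i]]$frames, sections(ph$series)[[i]]$frames)
    expect_identical(sections(s2)[[i]]$roi, sections(ph$series)[[i]]$roi)
    expect_equal(sections(s2)[[i]]$zcoord, sections(ph$series)[[i]]$zcoord)
  }
  expect_identical(s2@sectionLocations, ph$series@sectionLocations)
})

test_that("frame/label count mismatch is rejected at read time", {
  ph <- generateOEMRIPhantom(oemriPhantomConfig(framesPerPhase = 4, seed = 5))
  stem <- file.path(withr::local_tempdir(), "ser")
  writeOEMRISeries(ph$series, stem)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  meta$phaseLabels <- meta$phaseLabels[-1]
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE)
  expect_error(readOEMRISeries(stem), "phase labels")
})

test_that("cohort tables round-trip at full precision and validate schema", {
  coh <- generateCohort(cohortConfig(nCOPD = 5, nControl = 3, seed = 9))
  path <- file.path(withr::local_tempdir(), "coh.csv")
  writeCohortTable(coh$table, path)
  t2 <- readCohortTable(path)
  num <- vapply(coh$table, is.numeric, logical(1))
  relErr <- abs(as.matrix(t2[, num]) - as.matrix(coh$table[, num])) /
    pmax(abs(as.matrix(coh$table[, num])), 1e-300)
  expect_lt(max(relErr), 1e-14)

  # unknown column: warn but carry through
  t3 <- coh$table
  t3$extra <- 1
  expect_warning(writeCohortTable(t3, path), "unknown cohort columns")
  t4 <- suppressWarnings(readCohortTable(path))
  expect_true("extra" %in% names(t4))

  # duplicate ids and invalid groups are rejected
  t5 <- coh$table
  t5$id[2] <- t5$id[1]
  expect_error(writeCohortTable(t5, path), "duplicate")
  t6 <- coh$table
  t6$group[1] <- "patient"
  expect_error(writeCohortTable(t6, path), "group labels")
})

test_that("validation failures occur before any NIfTI is written", {
  ph <- generateCTPhantom(ctPhantomConfig(seed = 2))
  bad <- ph$volume
  expect_error(new("CTVolume", hu = huArray(bad)[, , 1:10],
                   spacing = voxelSpacing(bad), lungMask = lungMask(bad),
                   tracheaMask = tracheaMask(bad), calibrationShift = 0),
               "congruent")
})
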