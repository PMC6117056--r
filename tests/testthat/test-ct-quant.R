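test_that("calibration shifts tracheal mean to -1000 and records the shift", {
  ph <- noiselessCT(seed = 2)
  raw <- ph$volume
  # construct a volume whose tracheal mean is exactly -990
  hu <- huArray(raw)
  hu[tracheaMask(raw)] <- -990
  vol <- new("CTVolume", hu = hu, spacing = voxelSpacing(raw),
             lungMask = lungMask(raw), tracheaMask = tracheaMask(raw),
             calibrationShift = 0)
  cal <- calibrateHU(vol)
  expect_equal(calibrationShift(cal), -10)
  expect_equal(mean(huArray(cal)[tracheaMask(cal)]), -1000)
  # a voxel at -950 moves to -960 and is still NOT low attenuation
  probe <- which(lungMask(raw))[1]
  hu[probe] <- -950
  vol2 <- new("CTVolume", hu = hu, spacing = voxelSpacing(raw),
              lungMask = lungMask(raw), tracheaMask = tracheaMask(raw),
              calibrationShift = 0)
  cal2 <- calibrateHU(vol2)
  expect_equal(huArray(cal2)[probe], -960)
  expect_false(lavMask(cal2)[probe])

  # exactly -1000 tracheal mean: identity transform
  hu[tracheaMask(raw)] <- -1000
  vol3 <- new("CTVolume", hu = hu, spacing = voxelSpacing(raw),
              lungMask = lungMask(raw), tracheaMask = tracheaMask(raw),
              calibrationShift = 0)
  expect_equal(calibrationShift(calibrateHU(vol3)), 0)
  expect_identical(huArray(calibrateHU(vol3)), hu)
})

test_that("a grossly offset trachea mask triggers the suspect-mask warning", {
  ph <- noiselessCT(seed = 2)
  hu <- huArray(ph$volume) + 150
  vol <- new("CTVolume", hu = hu, spacing = voxelSpacing(ph$volume),
             lungMask = lungMask(ph$volume),
             tracheaMask = tracheaMask(ph$volume), calibrationShift = 0)
  expect_warning(calibrateHU(vol), "exceeds 100 HU")
})

test_that("LAV threshold is strict and restricted to the lung", {
  ph <- noiselessCT(seed = 3)
  vol <- calibrateHU(ph$volume)
  hu <- huArray(vol)
  lungIdx <- which(lungMask(vol))[1:3]
  hu[lungIdx] <- c(-960, -960.5, -959.9)
  outIdx <- which(!lungMask(vol) & !tracheaMask(vol))[1]
  hu[outIdx] <- -1000
  v <- new("CTVolume", hu = hu, spacing = voxelSpacing(vol),
           lungMask = lungMask(vol), tracheaMask = tracheaMask(vol),
           calibrationShift = 0)
  m <- lavMask(v)
  expect_identical(m[lungIdx], c(FALSE, TRUE, FALSE))
  expect_false(m[outIdx])
})

test_that("partition quotas follow the equal-count remainder rule", {
  expect_identical(lunghetero:::partitionQuotas(1200, 12), rep(100L, 12))
  expect_identical(lunghetero:::partitionQuotas(1201, 12),
                   c(101L, rep(100L, 11)))
  expect_identical(lunghetero:::partitionQuotas(1207, 12),
                   c(rep(101L, 7), rep(100L, 5)))
})

test_that("partitioning is isovolumetric, ordered cranial-caudal, and kept set is 2..11", {
  ph <- noiselessCT(seed = 5)
  scheme <- partitionIsovolumetric(ph$volume)
  expect_identical(scheme@nTotal, 12L)
  expect_identical(keptPartitions(scheme), 2:11)
  counts <- partitionCounts(scheme)
  expect_lte(max(counts) - min(counts), 1L)
  expect_identical(sum(counts), sum(lungMask(ph$volume)))
  # assignment follows the cranial-caudal voxel order
  d <- dim(huArray(ph$volume))
  z <- ((scheme@voxelIndex - 1L) %/% (d[1] * d[2])) + 1L
  expect_true(all(diff(z) >= 0))
  expect_true(all(diff(scheme@assignment) >= 0))
  # max-min over counts never exceeds the largest single-slice lung count
  sliceCounts <- apply(lungMask(ph$volume), 3, sum)
  expect_lte(max(counts) - min(counts), max(sliceCounts))
})

test_that("partitioning rejects degenerate requests", {
  ph <- noiselessCT(seed = 5)
  expect_error(partitionIsovolumetric(ph$volume, n = 2),
               "keeps nothing")
})

test_that("per-partition counts match a naive per-voxel loop (oracle)", {
  for (seed in c(1, 9)) {
    ph <- noiselessCT(target = 0.25, gradient = 0.4, seed = seed)
    vol <- calibrateHU(ph$volume)
    mask <- lavMask(vol)
    scheme <- partitionIsovolumetric(vol)
    oracle <- naivePartitionCounts(vol, mask, scheme)
    expect_identical(oracle$total, partitionCounts(scheme))
    pct <- lavPercentPerPartition(mask, scheme, keptOnly = FALSE)
    expect_equal(pct, 100 * oracle$lav / oracle$total, tolerance = 1e-12)
    # conservation: partition LAV counts sum to the whole-lung LAV count
    expect_identical(sum(oracle$lav), sum(mask))
  }
})

test_that("whole-lung LAV% equals the count-weighted mean of all 12 partitions", {
  ph <- noiselessCT(target = 0.3, gradient = 0.5, seed = 8)
  vol <- calibrateHU(ph$volume)
  res <- ctDensitometry(ph$volume)
  mask <- lavMask(vol)
  scheme <- partitionIsovolumetric(vol)
  pct <- lavPercentPerPartition(mask, scheme, keptOnly = FALSE)
  weighted <- sum(pct * partitionCounts(scheme)) / sum(partitionCounts(scheme))
  expect_equal(lavPercent(res), weighted, tolerance = 1e-9)
})

test_that("SD-LAV matches hand-computed sample SDs", {
  expect_equal(partitionSD(c(rep(0, 5), rep(20, 5))), sqrt(1000 / 9),
               tolerance = 1e-12)
  expect_equal(partitionSD(rep(10, 10)), 0)
  expect_equal(partitionSD(rep(c(5, 15), 5)), sqrt(250 / 9),
               tolerance = 1e-12)
  expect_equal(partitionSD(rep(c(5, 15), 5), denominator = "population"), 5)
})

test_that("noiseless phantom recovers the target fraction through the pipeline", {
  ph <- noiselessCT(target = 0.30, seed = 11)
  res <- ctDensitometry(ph$volume)
  expect_lt(abs(lavPercent(res) - 30), 0.5)
  # with zero HU noise the threshold mask equals the label mask exactly
  vol <- calibrateHU(ph$volume)
  expect_identical(lavMask(vol), emphysemaLabel(ph$truth))
})

test_that("calibration makes the result invariant to global HU offsets", {
  base <- generateCTPhantom(ctPhantomConfig(lavFractionTarget = 0.3,
                                            globalHUOffset = 0, seed = 13))
  res0 <- ctDensitometry(base$volume)
  for (off in c(-50, 15, 100)) {
    ph <- generateCTPhantom(ctPhantomConfig(lavFractionTarget = 0.3,
                                            globalHUOffset = off, seed = 13))
    res <- suppressWarnings(ctDensitometry(ph$volume))
    expect_equal(lavPercent(res), lavPercent(res0), tolerance = 1e-9)
    expect_equal(perPartition(res), perPartition(res0), tolerance = 1e-9)
    expect_equal(sdLav(res), sdLav(res0), tolerance = 1e-9)
  }
})
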