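test_that("phase windows take the steady-state tails of air1 and O2", {
  ph <- noiselessOEMRI(framesPerPhase = 10)
  win <- selectPhaseWindows(ph$series, 0.5)
  expect_identical(win$baseline, 6:10)
  expect_identical(win$enhanced, 16:20)
  winAll <- selectPhaseWindows(ph$series, 1.0)
  expect_identical(winAll$baseline, 1:10)
  expect_identical(winAll$enhanced, 11:20)
  expect_error(selectPhaseWindows(ph$series, 0), "windowFraction")
})

test_that("RER map implements the absolute-value percent-change formula", {
  roi <- matrix(TRUE, 2, 2)
  base <- matrix(100, 2, 2)
  enh <- matrix(c(120, 100, 80, 111), 2, 2)
  rm <- rerMap(base, enh, roi, floor = 1)
  expect_equal(rm$map[1, 1], 20)   # rise of 20%
  expect_equal(rm$map[2, 1], 0)    # no change
  expect_equal(rm$map[1, 2], 20)   # drop of 20% counts positive
  expect_equal(rm$map[2, 2], 11)
  expect_identical(rm$excluded, 0L)
})

test_that("low-baseline pixels are excluded and counted, empty ROI errors", {
  roi <- matrix(TRUE, 2, 2)
  base <- matrix(c(100, 0.5, 100, 100), 2, 2)
  rm <- rerMap(base, base * 1.2, roi, floor = 5)
  expect_identical(rm$excluded, 1L)
  expect_true(is.na(rm$map[2, 1]))
  expect_error(rerMap(matrix(0.1, 2, 2), matrix(1, 2, 2), roi, floor = 5),
               "below the baseline floor")
})

test_that("MRER is the pixel-weighted pooled mean across sections", {
  m1 <- matrix(10, 10, 10)   # 100 pixels at 10
  m2 <- matrix(20, 20, 15)   # 300 pixels at 20
  expect_equal(meanRER(list(m1, m2)), 17.5)
  expect_equal(meanRER(list(matrix(22, 5, 5))), 22)
})

test_that("SD-RER matches hand-computed partition SDs and pools sections", {
  # 10 rows, one partition per row, means alternating 5 and 15
  vals <- matrix(rep(c(5, 15), each = 4, times = 5), nrow = 10,
                 ncol = 4, byrow = TRUE)
  z <- seq_len(10)
  out <- sdRERPartitioned(list(vals), list(z), n = 10)
  expect_equal(out$perPartition, rep(c(5, 15), 5))
  expect_equal(out$sd, sqrt(250 / 9), tolerance = 1e-12)
  # uniform field: zero heterogeneity
  out0 <- sdRERPartitioned(list(matrix(7, 10, 4)), list(z), n = 10)
  expect_equal(out0$sd, 0)
  expect_error(sdRERPartitioned(list(matrix(7, 2, 2)), list(1:2), n = 10),
               "pooled ROI pixels")
})

test_that("noiseless amplitude is recovered as 100 a wbar within 1e-6 relative", {
  cfg <- oemriPhantomConfig(noiseSD = 0, enhancementGradient = 0,
                            framesPerPhase = 30, washinTimeConstant = 5)
  ph <- generateOEMRIPhantom(cfg)
  res <- rerAnalysis(ph$series)
  k <- 16:30  # enhanced window frames within the O2 phase
  wbar <- mean(1 - exp(-k / 5))
  expected <- 100 * 0.22 * wbar
  vals <- unlist(lapply(rerMaps(res), function(m) m[!is.na(m)]))
  expect_lt(max(abs(vals - expected) / expected), 1e-6)
  expect_equal(mrer(res), expected, tolerance = 1e-6)
  # enhanced-window mean sits within 0.1% of the asymptotic plateau
  expect_lt(abs(wbar - 1), 0.05)
  expect_equal(sdRer(res), 0, tolerance = 1e-9)
})

test_that("MRER equals the count-weighted mean of partition means", {
  ph <- generateOEMRIPhantom(oemriPhantomConfig(enhancementGradient = 0.5,
                                                seed = 3))
  res <- rerAnalysis(ph$series)
  maps <- rerMaps(res)
  nPix <- sum(vapply(maps, function(m) sum(!is.na(m)), numeric(1)))
  quotas <- lunghetero:::partitionQuotas(nPix, 10)
  weighted <- sum(perPartition(res) * quotas) / nPix
  expect_equal(mrer(res), weighted, tolerance = 1e-9)
})

test_that("COPD-like and control-like amplitudes reproduce the group ordering", {
  ctl <- noiselessOEMRI(amplitude = 0.22)
  cop <- noiselessOEMRI(amplitude = 0.126)
  mCtl <- mrer(rerAnalysis(ctl$series))
  mCop <- mrer(rerAnalysis(cop$series))
  expect_lt(mCop, mCtl)
  expect_equal(mCtl, 22.0, tolerance = 0.02)
  expect_equal(mCop, 12.6, tolerance = 0.02)
})

test_that("emphysema coupling lowers MRER in diseased phantoms", {
  healthy <- generateCTPhantom(ctPhantomConfig(lavFractionTarget = 0.02,
                                               seed = 21))
  diseased <- generateCTPhantom(ctPhantomConfig(lavFractionTarget = 0.45,
                                                seed = 21))
  mH <- mrer(rerAnalysis(generateOEMRIPhantom(
    oemriPhantomConfig(noiseSD = 0), truth = healthy$truth)$series))
  mD <- mrer(rerAnalysis(generateOEMRIPhantom(
    oemriPhantomConfig(noiseSD = 0), truth = diseased$truth)$series))
  expect_lt(mD, mH)
})
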