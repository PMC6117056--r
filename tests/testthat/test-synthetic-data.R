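test_that("phantom generation is deterministic in config and seed", {
  a <- generateCTPhantom(ctPhantomConfig(seed = 7))
  b <- generateCTPhantom(ctPhantomConfig(seed = 7))
  c <- generateCTPhantom(ctPhantomConfig(seed = 8))
  expect_identical(huArray(a$volume), huArray(b$volume))
  expect_identical(emphysemaLabel(a$truth), emphysemaLabel(b$truth))
  expect_false(identical(emphysemaLabel(a$truth), emphysemaLabel(c$truth)))

  m1 <- generateOEMRIPhantom(oemriPhantomConfig(seed = 5))
  m2 <- generateOEMRIPhantom(oemriPhantomConfig(seed = 5))
  expect_identical(sections(m1$series)[[1]]$frames,
                   sections(m2$series)[[1]]$frames)
})

test_that("zero target fraction places no emphysema at any gradient", {
  for (g in c(-0.5, 0, 0.8)) {
    ph <- generateCTPhantom(ctPhantomConfig(lavFractionTarget = 0,
                                            gradientStrength = g, seed = 3))
    expect_identical(sum(emphysemaLabel(ph$truth)), 0L)
    expect_identical(trueLavFraction(ph$truth), 0)
  }
})

test_that("realized fraction hits the target within half a point and recounts", {
  for (target in c(0.05, 0.30, 0.45)) {
    ph <- generateCTPhantom(ctPhantomConfig(lavFractionTarget = target,
                                            seed = 4))
    lung <- lungMask(ph$volume)
    recount <- sum(emphysemaLabel(ph$truth) & lung) / sum(lung)
    expect_identical(recount, trueLavFraction(ph$truth))
    expect_lt(abs(recount - target), 0.005)
    # per-partition truth recounts against the label volume
    scheme <- partitionIsovolumetric(ph$volume)
    frac <- vapply(seq_len(scheme@nTotal), function(p) {
      vx <- scheme@voxelIndex[scheme@assignment == p]
      mean(emphysemaLabel(ph$truth)[vx])
    }, numeric(1))
    expect_equal(frac, ph$truth@lavFractionPerPartition, tolerance = 1e-12)
  }
})

test_that("labels outside the lung never occur and masks stay disjoint", {
  ph <- generateCTPhantom(ctPhantomConfig(lavFractionTarget = 0.4, seed = 6))
  expect_false(any(emphysemaLabel(ph$truth) & !lungMask(ph$volume)))
  expect_false(any(lungMask(ph$volume) & tracheaMask(ph$volume)))
})

test_that("an oversized cluster radius raises an unreachable-target error", {
  expect_error(
    generateCTPhantom(ctPhantomConfig(voxelSpacing = c(0.7, 0.7, 0.5),
                                      clusterRadiusMM = 2.5, seed = 1)),
    "unreachable target fraction")
})

test_that("noiseless wash-in signal matches the closed-form curve", {
  cfg <- oemriPhantomConfig(noiseSD = 0, enhancementGradient = 0,
                            framesPerPhase = 12, washinTimeConstant = 4)
  ph <- generateOEMRIPhantom(cfg)
  fr <- sections(ph$series)[[1]]$frames
  a <- 0.22; tau <- 4; base <- 100
  expect_equal(fr[10, 10, 3], base)  # air1: no enhancement
  expect_equal(fr[10, 10, 12 + 7], base * (1 + a * (1 - exp(-7 / tau))),
               tolerance = 1e-12)
  wEnd <- 1 - exp(-12 / tau)
  expect_equal(fr[10, 10, 24 + 2], base * (1 + a * wEnd * exp(-2 / tau)),
               tolerance = 1e-12)
})

test_that("single-frame phases are a valid boundary case", {
  ph <- generateOEMRIPhantom(oemriPhantomConfig(framesPerPhase = 1L,
                                                noiseSD = 0))
  expect_identical(length(phaseLabels(ph$series)), 3L)
  expect_s4_class(ph$series, "OEMRISeries")
  res <- rerAnalysis(ph$series, windowFraction = 1)
  expect_gt(mrer(res), 0)
})

test_that("cohort covariates equal their linear predictors when noiseless", {
  ns <- list(fev1 = 0, dlco = 0, pao2 = 0, rvtlc = 0, sdlav = 0,
             sdrer = 0, lavPct = 0, fvc = 0, paco2 = 0)
  coh <- generateCohort(cohortConfig(nCOPD = 12, nControl = 5,
                                     noiseSD = ns, seed = 2))
  expect_equal(coh$table$dlco, pmax(coh$truth$dlco_mean, 2))
  expect_equal(coh$table$pao2, coh$truth$pao2_mean)
  expect_equal(coh$table$fev1_l, pmax(coh$truth$fev1_mean, 0.3))
  expect_equal(coh$table$lav_pct, 100 * coh$truth$lav_fraction)
})

test_that("cohort defaults mirror the study design and force the expected signs", {
  cfg <- cohortConfig()
  expect_identical(cfg$nCOPD, 40L)
  expect_identical(cfg$nControl, 9L)
  coh <- generateCohort(cohortConfig(seed = 17))
  copd <- coh$table[coh$table$group == "COPD", ]
  # DL_CO is linked negatively to the true emphysema fraction
  expect_lt(cor(copd$lav_pct, copd$dlco), 0)
  # COPD group has more emphysema and lower oxygen enhancement
  ctrl <- coh$table[coh$table$group == "control", ]
  expect_gt(mean(copd$lav_pct), mean(ctrl$lav_pct))
  expect_lt(mean(copd$mrer), mean(ctrl$mrer))
})
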