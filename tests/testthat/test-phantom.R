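test_that("phantom generation is deterministic given its seed", {
  s1 <- smallPhantomSpec(muscleHuSd = 5, noiseSdPet = 0.02, seed = 9L)
  a <- generatePhantom(s1)
  b <- generatePhantom(s1)
  expect_identical(voxelData(a$ct), voxelData(b$ct))
  expect_identical(voxelData(a$pet), voxelData(b$pet))
  s2 <- smallPhantomSpec(muscleHuSd = 5, noiseSdPet = 0.02, seed = 10L)
  expect_false(identical(voxelData(generatePhantom(s2)$ct),
                         voxelData(a$ct)))
})

test_that("truth masks agree with the analytic cylinder volume", {
  spec <- smallPhantomSpec()
  ph <- generatePhantom(spec)
  va <- phantomAnalyticVolume(spec)          # one side, full extent
  vm <- maskedVolume(ph$truth@ctMask, label = 1)
  # within one voxel layer of the boundary surface
  sliceArea <- vm / (diff(spec$muscleSliceRange) + 1) / spec$ctSpacing[1] * 1000
  layer <- 2 * sqrt(sliceArea * pi) * prod(spec$ctSpacing) / 1000 *
    (diff(spec$muscleSliceRange) + 1)
  expect_lt(abs(vm - va), layer)
  expect_equal(maskedVolume(ph$truth@ctMask, label = 1),
               maskedVolume(ph$truth@ctMask, label = 2), tolerance = 0.02)
})

test_that("zero SUV spread gives zero VC-SUV on the truth mask", {
  spec <- smallPhantomSpec(muscleSuvSd = 0)
  ph <- generatePhantom(spec)
  suv <- computeSUV(ph$pet, ph$meta)
  expect_equal(vcSuv(suv, ph$truth@petMask, spec$liverSuv), 0)
})

test_that("SUV-to-concentration conversion round-trips through computeSUV", {
  spec <- smallPhantomSpec()
  ph <- generatePhantom(spec)
  suv <- computeSUV(ph$pet, ph$meta)
  liv <- liverReference(suv, center = spec$liverCenter, diameterMm = 20)
  expect_equal(liv, spec$liverSuv, tolerance = 1e-12)
  mus <- voxelData(suv)[maskLabels(ph$truth@petMask) != 0L]
  expect_equal(mean(mus), spec$muscleSuvMean, tolerance = 0.02)
})

test_that("phantom geometry invariants hold and violations are caught", {
  spec <- smallPhantomSpec()
  ph <- generatePhantom(spec)
  ctArr <- voxelData(ph$ct)
  tm <- maskLabels(ph$truth@ctMask)
  expect_true(all(ctArr[tm != 0L] == spec$muscleHuMean))  # no overlap
  expect_error(phantomSpec(muscleCenterY = 120), "vertebral")
  expect_error(phantomSpec(liverAxes = c(24, 60, 36)), "liver")
})

test_that("simulated cohorts have the configured size and censoring", {
  ch <- generateCohort(n = 56, seed = 1)
  expect_equal(nrow(ch), 56)
  expect_true(all(ch$followup_months >= 0))
  expect_true(all(ch$event %in% 0:1))
  expect_true(all(ch$alsfrs_r >= 0 & ch$alsfrs_r <= 48))

  noCens <- generateCohort(n = 200, censoringRate = 0, seed = 2)
  expect_true(all(noCens$event == 1L))

  # default event fraction near the reference cohort's 37.5%
  evts <- vapply(1:20, function(s)
    mean(generateCohort(n = 200, seed = 100 + s)$event), numeric(1))
  expect_equal(mean(evts), 0.375, tolerance = 0.05)
})

test_that("null cohorts give hazard ratios near one", {
  hrs <- vapply(1:25, function(s) {
    ch <- generateCohort(n = 200, seed = 400 + s)
    coxUnivariate(ch, "psoas_n_suv")$result$hazard_ratio
  }, numeric(1))
  expect_equal(mean(log(hrs)), 0, tolerance = 0.1)
})

test_that("an effect on one variable is found by backward elimination", {
  bk <- simulateBackwardRetention(nRep = 10, seed = 7)
  expect_gte(bk$retainedTrue, 0.9)
})
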