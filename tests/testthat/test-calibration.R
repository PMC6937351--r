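test_that("decay correction obeys its closed form", {
  expect_equal(decayCorrect(370000, 0, 0), 370000)
  expect_equal(decayCorrect(370000, 0, 13.2213), 185000)
  ## 24 h delay at the I-123 half-life: 370000 * 2^(-24/13.2213),
  ## independently computed value
  expect_equal(decayCorrect(370000, 0, 24), 105137.2, tolerance = 1e-6)
  ## back-correction increases activity
  expect_gt(decayCorrect(1000, 5, 0), 1000)
  expect_error(decayCorrect(1, 0, 1, halfLife = 0), "positive")
})

test_that("decay correction composes over intermediate times", {
  set.seed(11)
  t0 <- as.POSIXct("2015-06-01 08:00", tz = "UTC")
  for (i in 1:20) {
    dt1 <- runif(1, -48, 48)
    dt2 <- runif(1, -48, 48)
    a <- runif(1, 1e3, 1e6)
    t1 <- t0 + dt1 * 3600
    t2 <- t0 + dt2 * 3600
    twoStep <- decayCorrect(decayCorrect(a, t0, t1), t1, t2)
    oneStep <- decayCorrect(a, t0, t2)
    expect_equal(twoStep, oneStep, tolerance = 1e-12)
  }
})

test_that("net injected activity subtracts the decay-corrected residual", {
  t0 <- as.POSIXct("2015-06-01 09:00", tz = "UTC")
  ## zero residual
  expect_equal(
    netInjectedActivity(doseRecord(370000, 0.0001, t0)),
    370000,
    tolerance = 1e-6
  )
  ## both assays at injection time: plain subtraction (the cohort median
  ## administered dose)
  expect_equal(netInjectedActivity(doseRecord(170000, 7200, t0)), 162800)
  ## assays away from injection time are referenced back to it
  rec <- doseRecord(170000, 7200, t0,
    preTime = t0 - 2 * 3600, postTime = t0 + 0.5 * 3600
  )
  hl <- iodine123HalfLife()
  expected <- 170000 * 2^(-2 / hl) - 7200 * 2^(0.5 / hl)
  expect_equal(netInjectedActivity(rec), expected, tolerance = 1e-12)
  ## impossible syringe
  expect_error(doseRecord(7200, 170000, t0), "exceed")
})

test_that("conversion factor round-trips a noise-free uniform cylinder", {
  prof <- noiseFreeProfile(psfFwhm = 8)
  cyl <- simulateUniformCylinder(111000, 6000, prof, spacing = 6)
  fac <- deriveConversionFactor(
    cyl$counts, 111000, 6000,
    prof@acquisitionSeconds
  )
  expect_false(fac@rateWarning)
  ## derivation consistency: factor * total counts = activity
  expect_equal(fac@kbqPerCount * fac@derivation$totalCounts, 111000,
    tolerance = 1e-9
  )
  cal <- applyCalibration(cyl$counts, fac)
  expect_identical(imageUnits(cal), "kBq_per_cm3")
  ## every deep-interior voxel recovers activity/volume to <0.1%
  interior <- measureVOI(cal, sphereVOI(c(0, 0, 0), 80, "core"))
  expect_lt(abs(interior$mean / 18.5 - 1), 0.001)
  expect_lt(abs(interior$max / 18.5 - 1), 0.001)
})

test_that("conversion factor is linear in activity and volume-independent", {
  prof <- noiseFreeProfile(psfFwhm = 6)
  f <- function(activity, volume) {
    cyl <- simulateUniformCylinder(activity, volume, prof, spacing = 6)
    deriveConversionFactor(
      cyl$counts, activity, volume,
      prof@acquisitionSeconds
    )@kbqPerCount
  }
  ## doubling the activity doubles the counts: identical factor
  expect_equal(f(50000, 6000), f(100000, 6000), tolerance = 1e-9)
  ## fixed sensitivity: the factor does not depend on phantom volume
  expect_equal(f(50000, 6000), f(50000, 3000), tolerance = 1e-3)
})

test_that("count-rate limit flags the derivation", {
  ## high-sensitivity profile pushes the rate beyond 20 kcts/s
  prof <- scannerProfile("hot", psfFwhm = 0, sensitivity = 0.5,
    acquisitionSeconds = 3360, noise = FALSE
  )
  cyl <- simulateUniformCylinder(111000, 6000, prof, spacing = 6)
  expect_warning(
    fac <- deriveConversionFactor(
      cyl$counts, 111000, 6000,
      prof@acquisitionSeconds
    ),
    "kcts/s"
  )
  expect_true(fac@rateWarning)
  expect_gte(fac@derivation$countRate, 20000)
})

test_that("calibration is linear and guards scanner identity", {
  prof <- noiseFreeProfile(psfFwhm = 5)
  cyl <- simulateUniformCylinder(20000, 6000, prof, spacing = 6)
  fac <- deriveConversionFactor(
    cyl$counts, 20000, 6000,
    prof@acquisitionSeconds
  )
  ## linearity: apply_calibration(k * counts) = k * apply_calibration(counts)
  k <- 3.7
  scaled <- ActivityImage(voxels(cyl$counts) * k,
    spacing = spacing(cyl$counts), units = "counts",
    origin = origin(cyl$counts), scanner = scannerName(cyl$counts)
  )
  expect_equal(
    voxels(applyCalibration(scaled, fac)),
    k * voxels(applyCalibration(cyl$counts, fac)),
    tolerance = 1e-12
  )
  ## all-zero counts stay all-zero
  zero <- ActivityImage(array(0, dim(voxels(cyl$counts))),
    spacing = spacing(cyl$counts), units = "counts"
  )
  expect_true(all(voxels(applyCalibration(zero, fac)) == 0))
  ## cross-scanner application is a configuration error
  other <- ActivityImage(voxels(cyl$counts),
    spacing = spacing(cyl$counts),
    units = "counts", scanner = "infinia_me"
  )
  expect_error(applyCalibration(other, fac), "cannot be applied")
})
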