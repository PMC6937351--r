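test_that("ground-truth voxelization reproduces the specified concentrations", {
  spec <- nemaPhantomSpec()
  truth <- buildGroundTruth(spec, spacing = 6)

  ## voxel at the 37-mm sphere center carries the sphere concentration
  big <- spec@spheres[spec@spheres$diameter == 37, ]
  m <- measureVOI(truth, sphereVOI(c(big$x, big$y, big$z), 6, "center"))
  expect_equal(m$mean, 35.4, tolerance = 1e-6)

  ## interior background VOI far from all inserts is exactly uniform
  bg <- measureVOI(truth, sphereVOI(c(-120, 0, 0), 25, "bg"))
  expect_equal(bg$mean, 11.0, tolerance = 1e-12)
  expect_equal(bg$max, 11.0, tolerance = 1e-12)

  ## lung insert is cold
  lung <- measureVOI(truth, sphereVOI(c(0, 0, 0), 30, "lung"))
  expect_equal(lung$max, 0, tolerance = 1e-12)

  ## outside the body is empty
  out <- measureVOI(truth, sphereVOI(c(165, 110, 0), 15, "out"))
  expect_equal(out$max, 0, tolerance = 1e-12)
})

test_that("all-zero concentrations give an all-zero image", {
  spec <- nemaPhantomSpec(
    sphereConcentration = 0,
    backgroundConcentration = 0
  )
  truth <- buildGroundTruth(spec, spacing = 7)
  expect_true(all(voxels(truth) == 0))
})

test_that("voxelized activity matches the analytic geometry integral to <1%", {
  spec <- nemaPhantomSpec()
  for (sp in c(4.8, 6)) {
    truth <- buildGroundTruth(spec, spacing = sp)
    total <- sum(voxels(truth)) * voxelVolume(truth)
    expect_lt(abs(total / analyticActivity(spec) - 1), 0.01)
  }
})

test_that("invalid geometry and spacing are rejected", {
  expect_error(
    buildGroundTruth(nemaPhantomSpec(), spacing = -1),
    "positive"
  )
  expect_error(
    buildGroundTruth(nemaPhantomSpec(), spacing = 12),
    "32 voxels"
  )
  ## overlapping spheres fail the specification validity check
  expect_error(
    nemaPhantomSpec(ringRadius = 8),
    "overlap"
  )
})

test_that("delta-PSF noise-free acquisition is proportional to truth", {
  truth <- tinyPhantomTruth()
  prof <- noiseFreeProfile(psfFwhm = 0)
  counts <- simulateAcquisition(truth, prof)
  scale <- prof@sensitivity * prof@acquisitionSeconds * voxelVolume(truth)
  expect_equal(voxels(counts), voxels(truth) * scale, tolerance = 1e-12)
  expect_identical(imageUnits(counts), "counts")
  expect_identical(scannerName(counts), "symbia_lehr")
})

test_that("Gaussian blur conserves total counts of interior objects", {
  truth <- tinyPhantomTruth()
  for (fwhm in c(8, 13, 20)) {
    prof <- noiseFreeProfile(psfFwhm = fwhm)
    counts <- simulateAcquisition(truth, prof)
    ref <- simulateAcquisition(truth, noiseFreeProfile(0))
    expect_lt(abs(sum(voxels(counts)) / sum(voxels(ref)) - 1), 0.001)
  }
})

test_that("peak sphere value is non-increasing in PSF width", {
  truth <- tinyPhantomTruth()
  spec <- nemaPhantomSpec()
  big <- spec@spheres[spec@spheres$diameter == 37, ]
  peaks <- vapply(c(0, 5, 10, 15, 20), function(fwhm) {
    img <- simulateAcquisition(truth, noiseFreeProfile(fwhm))
    measureVOI(img, sphereVOI(c(big$x, big$y, big$z), 37, "s"))$max
  }, numeric(1))
  expect_true(all(diff(peaks) <= 1e-9))
})

test_that("seeded acquisitions are bit-identical and seeds differ", {
  truth <- tinyPhantomTruth()
  prof <- defaultScannerProfile("symbia_lehr")
  a <- simulateAcquisition(truth, prof, seed = 42)
  b <- simulateAcquisition(truth, prof, seed = 42)
  c <- simulateAcquisition(truth, prof, seed = 43)
  expect_identical(voxels(a), voxels(b))
  expect_false(identical(voxels(a), voxels(c)))
})

test_that("Poisson counting matches its expectation over repeated seeds", {
  ## small uniform block: sum of k independent Poisson draws per voxel is
  ## Poisson(k * lambda); chi-square GOF should not reject at alpha = 0.01
  truth <- ActivityImage(array(10, c(6, 6, 6)), spacing = 8)
  prof <- scannerProfile("s", psfFwhm = 0, sensitivity = 0.01,
    acquisitionSeconds = 100, noise = TRUE
  )
  lambda <- 0.01 * 100 * voxelVolume(truth) * 10
  k <- 200
  sums <- Reduce(`+`, lapply(seq_len(k), function(s) {
    voxels(simulateAcquisition(truth, prof, seed = 3000 + s))
  }))
  z <- (sums - k * lambda) / sqrt(k * lambda)
  chi2 <- sum(z^2)
  n <- length(z)
  expect_gt(pchisq(chi2, df = n, lower.tail = FALSE), 0.01)
})

test_that("negative truth voxels are rejected by the forward model", {
  bad <- ActivityImage(array(c(-1, rep(1, 26)), c(3, 3, 3)), spacing = 8)
  expect_error(
    simulateAcquisition(bad, noiseFreeProfile(0)),
    "negative"
  )
})

test_that("uniform cylinder simulation reports the true concentration", {
  prof <- noiseFreeProfile(0)
  cyl <- simulateUniformCylinder(111000, 6000, prof, spacing = 6)
  expect_equal(cyl$truthConcentration, 18.5)
  cyl2 <- simulateUniformCylinder(4242, 4242, prof, spacing = 8,
    radius = 80
  )
  expect_equal(cyl2$truthConcentration, 1)
  expect_error(simulateUniformCylinder(-1, 10, prof), "positive")
  expect_error(simulateUniformCylinder(10, 0, prof), "positive")
})

test_that("tissue cohort draws follow their generating distributions", {
  ## degenerate SD: every draw equals the mean
  spec0 <- cohortSpec(
    tissues = data.frame(
      tissue = "liver", scanner = c("a", "b"), mean = 1.6, sd = 0,
      n = 10
    ),
    tumorNoiseSD = 0, liverReference = c(2.1, 0)
  )
  sim0 <- simulatePatientCohort(spec0, seed = 1)
  expect_true(all(sim0$tissues$suv == 1.6))
  expect_equal(seriesData(sim0$series)$tumor_suvmax,
    spec0@tumorTrajectory$suvmax,
    tolerance = 1e-12
  )

  ## liver 1.6 +/- 0.5 at n = 1000: sample mean within 0.05
  spec1 <- cohortSpec(tissues = data.frame(
    tissue = "liver", scanner = c("a", "b"), mean = 1.6, sd = 0.5,
    n = 1000
  ))
  sim1 <- simulatePatientCohort(spec1, seed = 99)
  expect_lt(abs(mean(sim1$tissues$suv) - 1.6), 0.05)
  expect_true(all(sim1$tissues$suv >= 0))

  ## same seed reproduces the cohort exactly
  sim2 <- simulatePatientCohort(spec1, seed = 99)
  expect_identical(sim1$tissues, sim2$tissues)
  expect_identical(seriesData(sim1$series), seriesData(sim2$series))
})

test_that("liver cohort generator gives every patient both scanners", {
  liver <- simulateLiverCohort(seed = 8)
  expect_equal(length(unique(liver$patient_id)), 28L)
  byPatient <- split(liver$scanner, liver$patient_id)
  expect_true(all(vapply(byPatient, function(s) {
    length(unique(s)) == 2L
  }, logical(1))))
  expect_true(all(table(liver$patient_id) >= 2L))
})
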