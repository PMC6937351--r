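test_that("VOI measurement: uniform, hot-voxel and brute-force membership", {
  img <- ActivityImage(array(7, c(20, 20, 20)), spacing = 4.8)
  m <- measureVOI(img, sphereVOI(c(0, 0, 0), 30, "u"))
  expect_equal(m$mean, 7)
  expect_equal(m$max, 7)

  v <- array(1, c(20, 20, 20))
  v[10, 10, 10] <- 100
  hot <- ActivityImage(v, spacing = 4.8)
  o <- origin(hot)
  hotCenter <- o + (c(10, 10, 10) - 1) * 4.8
  mh <- measureVOI(hot, sphereVOI(hotCenter, 20, "hot"))
  expect_equal(mh$max, 100)

  ## n_voxels agrees with an exhaustive voxel-center count
  center <- c(3, -2, 5)
  m30 <- measureVOI(img, sphereVOI(center, 30, "count"))
  grid <- expand.grid(
    x = o[1] + (0:19) * 4.8, y = o[2] + (0:19) * 4.8,
    z = o[3] + (0:19) * 4.8
  )
  inside <- (grid$x - center[1])^2 + (grid$y - center[2])^2 +
    (grid$z - center[3])^2 <= 15^2
  expect_equal(m30$nVoxels, sum(inside))

  ## out-of-bounds and empty VOIs are errors
  expect_error(measureVOI(img, sphereVOI(c(90, 0, 0), 30, "oob")), "beyond")
  expect_error(measureVOI(img, sphereVOI(c(1, 1, 1), 1, "tiny")),
    "no voxel"
  )
})

test_that("SUV follows Av / (A/w)", {
  expect_equal(computeSUV(6.6375, 106200, 16000), 1)
  expect_equal(computeSUV(0, 106200, 16000), 0)
  ## phantom worked example: 35.4 kBq/cm3, 106,200 kBq, 16 kg
  expect_equal(computeSUV(35.4, 106200, 16000), 5.3333, tolerance = 1e-4)
  expect_error(computeSUV(1, 0, 1), "positive")
  expect_error(computeSUV(1, 1, -5), "positive")
})

test_that("CRC follows its contrast-ratio definition", {
  expect_equal(computeCRC(3.2182, 1, 35.4, 11.0), 1, tolerance = 1e-4)
  expect_equal(computeCRC(1.5, 1.5, 35.4, 11.0), 0)
  expect_equal(computeCRC(2, 1, 35.4, 11.0), 0.4509, tolerance = 3e-4)
  expect_error(computeCRC(1, 1, 10, 10), "undefined")
  expect_error(computeCRC(1, 0, 35.4, 11), "positive")
})

test_that("recovered activity applies the 1 + (1 - CRC) correction", {
  ## CRC = 1 reduces to the plain SUV inversion
  expect_equal(recoverActivity(5, 1000, 500, 1), 5 * 2)
  expect_equal(recoverActivity(2, 1000, 1000, 0.5), 3)
  ## the 37-mm worked result: SUV 4.9661 at A/w = 6.6375, CRC 0.82
  expect_equal(recoverActivity(4.9661, 106200, 16000, 0.82), 38.9,
    tolerance = 1e-3
  )
  expect_error(recoverActivity(1, -1, 1, 1), "positive")
  expect_error(recoverActivity(1, 1, 1, -0.1), ">= 0")
  expect_warning(recoverActivity(1, 1, 1, 1.2), "clamping")
})

test_that("quantitation formulas agree with independent arithmetic on random inputs", {
  set.seed(7)
  for (i in 1:200) {
    s <- runif(1, 0.1, 10)
    b <- runif(1, 0.1, 5)
    as <- runif(1, 10, 50)
    ab <- runif(1, 1, 9)
    crc <- computeCRC(s, b, as, ab)
    ## independent form: ((s - b) * ab) / (b * (as - ab))
    expect_equal(crc, ((s - b) * ab) / (b * (as - ab)), tolerance = 1e-12)

    inj <- runif(1, 1e4, 1e6)
    w <- runif(1, 5e3, 9e4)
    cr <- runif(1, 0, 1)
    rec <- recoverActivity(s, inj, w, cr)
    expect_equal(rec, (2 * s - s * cr) * inj / w, tolerance = 1e-12)

    ## inverse consistency: SUV then recovery at CRC = 1 returns Av
    av <- runif(1, 0.1, 50)
    expect_equal(
      recoverActivity(computeSUV(av, inj, w), inj, w, 1), av,
      tolerance = 1e-12
    )
  }
})

test_that("recovered activity is strictly decreasing in CRC", {
  crcs <- seq(0, 1, by = 0.05)
  rec <- suppressWarnings(recoverActivity(3, 1e5, 2e4, crcs))
  expect_true(all(diff(rec) < 0))
})

test_that("percent error matches the reporting convention", {
  expect_equal(percentError(33.5, 35.4), -5.367, tolerance = 1e-3)
  expect_equal(percentError(33.5, 35.4, reported = TRUE), -5)
  expect_equal(percentError(4.2, 4.2), 0)
  expect_equal(percentError(11.7, 11.0), 6.364, tolerance = 1e-3)
  expect_equal(percentError(11.7, 11.0, reported = TRUE), 6)
  ## rounding is symmetric away from zero
  expect_equal(percentError(1.016, 1, reported = TRUE), 2)
  expect_equal(percentError(0.984, 1, reported = TRUE), -2)
  expect_error(percentError(1, 0), "positive")
})
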