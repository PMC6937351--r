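test_that("scanner comparison handles identity, separation and mismatch", {
  set.seed(2)
  cohort <- data.frame(
    tissue = rep(c("liver", "bladder"), each = 20),
    suv = c(rnorm(20, 1.6, 0.5), rnorm(20, 4.4, 1.5))
  )
  ## a cohort compared with itself: every p = 1
  self <- compareScanners(cohort, cohort)
  expect_equal(self$p, rep(1, 2))
  expect_equal(attr(self, "averageP"), 1)

  ## disjoint supports at the parotid sample sizes: overwhelming evidence
  a <- data.frame(tissue = "r_parotid", suv = rnorm(16, 2, 0.1))
  b <- data.frame(tissue = "r_parotid", suv = rnorm(14, 10, 0.1))
  sep <- compareScanners(a, b)
  expect_lt(sep$p, 0.001)
  expect_true(sep$significant)

  ## label mismatch is a data error
  c1 <- data.frame(tissue = "liver", suv = rnorm(5))
  c2 <- data.frame(tissue = "spleen", suv = rnorm(5))
  expect_error(compareScanners(c1, c2), "tissue labels")
})

test_that("IQR summary follows the linear-interpolation convention", {
  s <- iqrSummary(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$iqr, 2)
  expect_length(s$outliers, 0)

  const <- iqrSummary(rep(2.5, 10))
  expect_equal(const$iqr, 0)
  expect_length(const$outliers, 0)

  out <- iqrSummary(c(1, 2, 3, 4, 100))
  expect_equal(out$outliers, 100)
  expect_equal(out$whiskers, c(1, 4))
})

test_that("intrapatient variability reproduces the min/max ratio convention", {
  ## two patients pinned at the cohort extremes
  liver <- data.frame(
    patient_id = rep(c("lo", "hi"), each = 2),
    liver_mean_suv = c(0.5, 0.5, 3.2, 3.2)
  )
  v <- intrapatientVariability(liver)
  expect_equal(v$min, 0.5)
  expect_equal(v$max, 3.2)
  expect_equal(v$percent, 100 * 0.5 / 3.2, tolerance = 1e-12)
  expect_equal(v$reportedPercent, 16)

  ## identical patients: ratio 100%, zero variance
  same <- data.frame(
    patient_id = rep(c("a", "b"), each = 3),
    liver_mean_suv = rep(1.7, 6)
  )
  vs <- intrapatientVariability(same)
  expect_equal(vs$percent, 100)
  expect_equal(vs$varianceOfMeans, 0)

  ## single-study patients are excluded with a warning
  mixed <- rbind(liver, data.frame(patient_id = "solo", liver_mean_suv = 2))
  expect_warning(vm <- intrapatientVariability(mixed), "fewer than 2")
  expect_equal(nrow(vm$perPatient), 2L)
})

test_that("synthetic liver cohort recovers its generating mean", {
  liver <- simulateLiverCohort(
    nPatients = 28, studiesPerPatient = 3,
    mean = 1.6, sd = 0.5, seed = 4
  )
  v <- intrapatientVariability(liver)
  expect_lt(abs(v$cohortMean - 1.6), 0.15)
  expect_gt(v$varianceOfMeans, 0)
})

test_that("percent reduction matches the worked trajectory numbers", {
  s <- longitudinalSeries(
    "p", c(0, 73), c(12.0, 3.1), c(2.1, 2.1),
    "symbia_lehr"
  )
  expect_equal(percentReduction(s), 100 * (1 - 3.1 / 12), tolerance = 1e-12)
  expect_equal(percentReduction(s, reported = TRUE), 74)

  flat <- longitudinalSeries("p", c(0, 1), c(5, 5), c(2, 2), "s")
  expect_equal(percentReduction(flat), 0)
  gone <- longitudinalSeries("p", c(0, 1), c(5, 0), c(2, 2), "s")
  expect_equal(percentReduction(gone), 100)
  zeroBase <- longitudinalSeries("p", c(0, 1), c(0, 5), c(2, 2), "s")
  expect_error(percentReduction(zeroBase), "baseline")
})

test_that("trajectory report summarizes scanner segments and percent change", {
  s <- longitudinalSeries(
    "p", c(0, 5, 10, 15), c(10, 8, 6, 4),
    c(2.1, 2.1, 1.9, 2.3),
    c("infinia_me", "infinia_me", "symbia_lehr", "symbia_lehr")
  )
  rep <- trajectoryReport(s)
  expect_equal(nrow(rep$liverSegments), 2L)
  expect_equal(rep$liverSegments$mean, c(2.1, 2.1))
  expect_equal(rep$liverSegments$sd[1], 0)
  ## monotone decreasing tumor gives monotone decreasing percent change
  expect_true(all(diff(rep$table$pct_change_from_baseline) < 0))

  ## increasing relapse-style series: +350% and +529% from baseline
  up <- longitudinalSeries(
    "p", c(0, 5, 10), c(3.8, 17.1, 23.9),
    c(2, 2, 2), "s"
  )
  pc <- trajectoryReport(up)$table$pct_change_from_baseline
  expect_equal(pc[2], 350, tolerance = 0.5)
  expect_equal(pc[3], 529, tolerance = 0.5)
})
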