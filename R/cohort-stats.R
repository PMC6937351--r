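## Cohort-level statistics: scanner comparison, IQR summaries,
## intrapatient liver variability, longitudinal tumor response.

#' Compare per-tissue SUV distributions between two scanners
#'
#' Runs a two-tailed Mann-Whitney U test per tissue and summarizes with
#' the cross-tissue average p-value. Both cohorts must cover the same
#' tissue labels.
#'
#' @param cohortA,cohortB `data.frame`s with columns `tissue` and `suv`
#'   (one row per measurement), e.g. the `tissues` element of
#'   [simulatePatientCohort()] split by scanner.
#' @param ... Passed to [mannWhitneyU()] (e.g. `mode`, `exactLimit`).
#' @return `data.frame` with one row per tissue: `tissue`, `n1`,
#'   `mean1`, `sd1`, `n2`, `mean2`, `sd2`, `u`, `p` (3 decimals on print
#'   surfaces; stored full precision), `method`, `significant` (at the
#'   0.05 level). The cross-tissue mean p-value is attached as attribute
#'   `averageP`.
#' @export
#' @examples
#' cohort <- simulatePatientCohort(cohortSpec(), seed = 3)$tissues
#' a <- cohort[cohort$scanner == "infinia_me", ]
#' b <- cohort[cohort$scanner == "symbia_lehr", ]
#' cmp <- compareScanners(a, b)
#' attr(cmp, "averageP")
compareScanners <- function(cohortA, cohortB, ...) {
  for (d in list(cohortA, cohortB)) {
    if (!all(c("tissue", "suv") %in% names(d))) {
      stop("cohorts need columns 'tissue' and 'suv'", call. = FALSE)
    }
  }
  labsA <- sort(unique(cohortA$tissue))
  labsB <- sort(unique(cohortB$tissue))
  if (!identical(labsA, labsB)) {
    stop("cohorts cover different tissue labels", call. = FALSE)
  }
  rows <- lapply(labsA, function(lab) {
    xa <- cohortA$suv[cohortA$tissue == lab]
    xb <- cohortB$suv[cohortB$tissue == lab]
    res <- mannWhitneyU(xa, xb, ...)
    data.frame(
      tissue = lab,
      n1 = length(xa), mean1 = mean(xa), sd1 = sd(xa),
      n2 = length(xb), mean2 = mean(xb), sd2 = sd(xb),
      u = res$u, p = res$p, method = res$method,
      significant = res$p < 0.05
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "averageP") <- mean(out$p)
  out
}

#' Interquartile summary with Tukey-fence outliers
#'
#' Quartiles by linear interpolation (type 7, the plotting convention);
#' whiskers reach the most extreme observations within 1.5 IQR of the
#' quartiles and anything beyond is flagged as an outlier.
#'
#' @param sample Non-empty numeric sample.
#' @return List with `median`, `q1`, `q3`, `iqr`, `whiskers`
#'   (`c(lower, upper)`) and `outliers`.
#' @export
#' @examples
#' iqrSummary(c(1, 2, 3, 4, 100))
iqrSummary <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) == 0L || any(!is.finite(sample))) {
    stop("'sample' must be non-empty and finite", call. = FALSE)
  }
  q <- quantile(sample, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lowFence <- q[1] - 1.5 * iqr
  highFence <- q[3] + 1.5 * iqr
  inside <- sample >= lowFence & sample <= highFence
  list(
    median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
    whiskers = c(min(sample[inside]), max(sample[inside])),
    outliers = sort(sample[!inside])
  )
}

#' Intrapatient liver SUV variability across scanners
#'
#' Averages each patient's mean liver SUV over their studies, then
#' summarizes the cohort: the overall minimum and maximum per-patient
#' mean, their ratio as a percentage (the headline variability figure,
#' reported rounded to integer percent), the cohort average of the
#' per-patient means and the variance of those means. Patients with
#' fewer than two studies are excluded with a warning.
#'
#' @param liver `data.frame` with columns `patient_id` and
#'   `liver_mean_suv` (one row per study), e.g. from
#'   [simulateLiverCohort()].
#' @return List with `perPatient` (`data.frame`: `patient_id`,
#'   `n_studies`, `mean_suv`), `min`, `max`, `percent`
#'   (`100 * min/max`), `reportedPercent`, `cohortMean` and
#'   `varianceOfMeans`.
#' @export
#' @examples
#' liver <- simulateLiverCohort(seed = 5)
#' intrapatientVariability(liver)$reportedPercent
intrapatientVariability <- function(liver) {
  if (!all(c("patient_id", "liver_mean_suv") %in% names(liver))) {
    stop("'liver' needs columns 'patient_id' and 'liver_mean_suv'",
      call. = FALSE
    )
  }
  counts <- table(liver$patient_id)
  tooFew <- names(counts)[counts < 2]
  if (length(tooFew)) {
    warning(sprintf(
      "excluding %d patient(s) with fewer than 2 studies: %s",
      length(tooFew), paste(tooFew, collapse = ", ")
    ), call. = FALSE)
    liver <- liver[!liver$patient_id %in% tooFew, , drop = FALSE]
  }
  if (!nrow(liver)) {
    stop("no patients with at least 2 studies", call. = FALSE)
  }
  means <- tapply(liver$liver_mean_suv, liver$patient_id, mean)
  perPatient <- data.frame(
    patient_id = names(means),
    n_studies = as.integer(table(liver$patient_id)[names(means)]),
    mean_suv = as.numeric(means)
  )
  lo <- min(perPatient$mean_suv)
  hi <- max(perPatient$mean_suv)
  pct <- 100 * lo / hi
  list(
    perPatient = perPatient,
    min = lo, max = hi,
    percent = pct,
    reportedPercent = roundHalfAway(pct),
    cohortMean = mean(perPatient$mean_suv),
    varianceOfMeans = if (nrow(perPatient) > 1L) {
      var(perPatient$mean_suv)
    } else {
      0
    }
  )
}

#' Percent reduction of tumor SUVmax between two time points
#'
#' `100 * (1 - suvmax[to]/suvmax[from])`; a negative value is an
#' increase.
#'
#' @param series A [LongitudinalSeries-class].
#' @param from,to Time-point indices (default baseline to last).
#' @param reported Round to integer percent.
#' @return Percent reduction.
#' @export
#' @examples
#' s <- longitudinalSeries("p1", c(0, 73), c(12.0, 3.1), c(2.1, 2.1), "s")
#' percentReduction(s, reported = TRUE) # 74
percentReduction <- function(series, from = 1L,
                             to = nrow(seriesData(series)),
                             reported = FALSE) {
  d <- seriesData(series)
  if (from < 1L || to > nrow(d)) {
    stop("time-point indices out of range", call. = FALSE)
  }
  base <- d$tumor_suvmax[from]
  if (base <= 0) {
    stop("baseline SUVmax must be positive", call. = FALSE)
  }
  red <- 100 * (1 - d$tumor_suvmax[to] / base)
  if (reported) roundHalfAway(red) else red
}

#' Longitudinal trajectory report
#'
#' Per-time-point tumor SUVmax with cumulative percent change from
#' baseline, plus per-scanner-segment liver reference summaries
#' (mean +/- SD of the liver mean SUV over the contiguous time points
#' acquired on each scanner).
#'
#' @param series A [LongitudinalSeries-class].
#' @return List with `table` (`data.frame`: `week`, `tumor_suvmax`,
#'   `liver_mean_suv`, `scanner`, `pct_change_from_baseline`) and
#'   `liverSegments` (`data.frame`: `scanner`, `weeks`, `n`, `mean`,
#'   `sd`).
#' @export
#' @examples
#' s <- simulatePatientCohort(cohortSpec(), seed = 2)$series
#' trajectoryReport(s)$liverSegments
trajectoryReport <- function(series) {
  stopifnot(is(series, "LongitudinalSeries"))
  d <- seriesData(series)
  base <- d$tumor_suvmax[1]
  pct <- if (base > 0) 100 * (d$tumor_suvmax / base - 1) else NA_real_
  tab <- cbind(d, pct_change_from_baseline = pct)
  ## contiguous scanner segments
  seg <- cumsum(c(TRUE, d$scanner[-1] != d$scanner[-nrow(d)]))
  segs <- lapply(split(seq_len(nrow(d)), seg), function(idx) {
    data.frame(
      scanner = d$scanner[idx[1]],
      weeks = sprintf("%g-%g", min(d$week[idx]), max(d$week[idx])),
      n = length(idx),
      mean = mean(d$liver_mean_suv[idx]),
      sd = if (length(idx) > 1L) sd(d$liver_mean_suv[idx]) else 0
    )
  })
  liverSegments <- do.call(rbind, segs)
  rownames(liverSegments) <- NULL
  list(table = tab, liverSegments = liverSegments)
}
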