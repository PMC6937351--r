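## Synthetic two-scanner patient cohorts: per-tissue SUV samples drawn
## from truncated-at-zero normals, repeated liver measurements for the
## intrapatient-variability analysis, and a longitudinal tumor series.

## truncated-at-zero normal draws by rejection; sd = 0 degenerates to the
## mean. The default tissue parameters keep the truncation mass tiny, so
## sample means track the generating means.
rtruncNorm0 <- function(n, mean, sd) {
  if (sd == 0) {
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(n - length(out), mean, sd)
    out <- c(out, draw[draw >= 0])
  }
  out
}

#' Simulate a two-scanner patient cohort
#'
#' Draws per-tissue mean-SUV samples for every tissue/scanner
#' distribution in the cohort specification (truncated-at-zero normal
#' with the specified mean and SD) and one longitudinal tumor series
#' (trajectory value plus Gaussian measurement noise, liver reference
#' drawn per time point). Fully seeded and reproducible.
#'
#' @param spec A [CohortSpec-class].
#' @param seed Integer seed; defaults to the spec's seed.
#' @return A list with elements `tissues` (`data.frame` with columns
#'   `tissue`, `scanner`, `suv`) and `series` (a
#'   [LongitudinalSeries-class]).
#' @seealso [cohortSpec()], [simulateLiverCohort()]
#' @export
#' @examples
#' cohort <- simulatePatientCohort(cohortSpec(), seed = 7)
#' head(cohort$tissues)
#' cohort$series
simulatePatientCohort <- function(spec, seed = NULL) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  if (is.null(seed)) seed <- spec@seed
  withSeed(seed, {
    ts <- spec@tissues
    samples <- lapply(seq_len(nrow(ts)), function(i) {
      data.frame(
        tissue = ts$tissue[i], scanner = ts$scanner[i],
        suv = rtruncNorm0(ts$n[i], ts$mean[i], ts$sd[i])
      )
    })
    tissues <- do.call(rbind, samples)
    tr <- spec@tumorTrajectory
    k <- nrow(tr)
    tumorObs <- pmax(tr$suvmax + rnorm(k, 0, spec@tumorNoiseSD), 0)
    liverObs <- rtruncNorm0(k, spec@liverReference[1], spec@liverReference[2])
    series <- longitudinalSeries(
      subject = "sim_patient_01", week = tr$week,
      tumorSuvmax = tumorObs, liverMeanSuv = liverObs,
      scanner = tr$scanner
    )
    list(tissues = tissues, series = series)
  })
}

#' Simulate repeated liver measurements for an intrapatient cohort
#'
#' Generates per-study mean liver SUVs for a cohort of patients each
#' imaged two or more times across two scanners, for the
#' intrapatient-variability analysis. The default study-count mixture
#' (two studies for 6 patients, three for 14, four for 5, and one patient
#' each with five, six and ten studies) mirrors a realistic serial-imaging
#' caseload; each patient's studies alternate between the two scanners so
#' every patient is seen on both.
#'
#' @param nPatients Number of patients.
#' @param studiesPerPatient Integer vector of per-patient study counts
#'   (recycled/truncated to `nPatients`); all entries must be >= 2.
#' @param mean,sd Generating liver mean-SUV distribution (truncated at
#'   zero).
#' @param scanners Two scanner labels to alternate between.
#' @param seed Integer seed.
#' @return `data.frame` with columns `patient_id`, `study`, `scanner`,
#'   `liver_mean_suv`.
#' @seealso [intrapatientVariability()]
#' @export
#' @examples
#' liver <- simulateLiverCohort(seed = 11)
#' head(liver)
simulateLiverCohort <- function(nPatients = 28,
                                studiesPerPatient = NULL,
                                mean = 1.6, sd = 0.5,
                                scanners = c("infinia_me", "symbia_lehr"),
                                seed = NULL) {
  if (is.null(studiesPerPatient)) {
    studiesPerPatient <- rep(c(2L, 3L, 4L, 5L, 6L, 10L), c(6, 14, 5, 1, 1, 1))
  }
  studiesPerPatient <- rep_len(as.integer(studiesPerPatient), nPatients)
  if (any(studiesPerPatient < 2L)) {
    stop("every patient needs at least 2 studies", call. = FALSE)
  }
  withSeed(seed, {
    rows <- lapply(seq_len(nPatients), function(p) {
      k <- studiesPerPatient[p]
      data.frame(
        patient_id = sprintf("patient_%02d", p),
        study = seq_len(k),
        scanner = rep_len(scanners, k),
        liver_mean_suv = rtruncNorm0(k, mean, sd)
      )
    })
    do.call(rbind, rows)
  })
}
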