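## Umbrella workflows: the phantom accuracy study and the cohort
## analysis, each a thin deterministic chain over the stage functions,
## with optional CSV/JSON outputs and a run manifest.

#' Assemble a pipeline configuration
#'
#' Collects every tunable of the two workflows with the package defaults:
#' the NEMA IEC phantom filled at 35.4 / 11.0 kBq cm^-3, a 111 MBq /
#' 6000 cm^3 calibration cylinder, net phantom activity 106,200 kBq and
#' phantom weight 16,000 g for the SUV denominator, 4.8 mm voxels, the
#' `"symbia_lehr"` default scanner profile, 12 background VOIs of 30 mm
#' with 25 mm clearance, visibility threshold 2 background SDs, and the
#' statistics options (exact-test size limit 12, alpha 0.05). One global
#' `seed` fans out deterministically to the simulation stages.
#'
#' @param ... Overrides for any configuration field.
#' @return A list of class `"qspectConfig"`.
#' @export
#' @examples
#' cfg <- pipelineConfig(seed = 42)
#' names(cfg)
pipelineConfig <- function(...) {
  cfg <- list(
    spacing = 4.8,
    profile = defaultScannerProfile("symbia_lehr"),
    phantom = nemaPhantomSpec(),
    cylinderActivity = 111000, # kBq
    cylinderVolume = 6000, # cm^3
    injected = 106200, # kBq net phantom activity
    weight = 16000, # g
    voiScale = 1,
    nBackground = 12L,
    backgroundDiameter = 30,
    clearance = 25,
    visibilityK = 2,
    halfLife = iodine123HalfLife(),
    cohort = cohortSpec(),
    liverMean = 1.6,
    liverSD = 0.5,
    exactLimit = 12L,
    alpha = 0.05,
    seed = 1L,
    outDir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop(sprintf(
      "unknown configuration field(s): %s", paste(unknown, collapse = ", ")
    ), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  }
  class(cfg) <- "qspectConfig"
  cfg
}

configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(cfg, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

writeManifest <- function(outDir, cfg, stages) {
  manifest <- list(
    package = "qspect",
    version = as.character(packageVersion("qspect")),
    seed = cfg$seed,
    stage_seeds = stages,
    config_md5 = configHash(cfg)
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
}

#' Run the phantom accuracy study
#'
#' The full quantitative-accuracy chain: simulate the uniform calibration
#' cylinder, derive the kBq-per-count conversion factor, simulate the
#' body-phantom acquisition, calibrate it back to concentration units,
#' and run the sphere-by-sphere CRC / recovered-activity analysis. When
#' `config$outDir` is set, writes `crc_results.csv`,
#' `conversion_factor.json` and `manifest.json` there.
#'
#' @param config A [pipelineConfig()] list.
#' @return List with `factor` (the [CalibrationFactor-class]), `results`
#'   (the [crcAnalysis()] table), `calibrated` (the calibrated
#'   [ActivityImage-class]) and `truth`.
#' @export
#' @examples
#' cfg <- pipelineConfig(
#'   spacing = 6,
#'   profile = defaultScannerProfile(noiseOn = FALSE)
#' )
#' study <- runPhantomStudy(cfg)
#' study$results[, c("label", "visible", "crc", "percent_error")]
runPhantomStudy <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "qspectConfig"))
  seeds <- list(
    cylinder = stageSeed(config$seed, 1L),
    phantom = stageSeed(config$seed, 2L)
  )
  cyl <- simulateUniformCylinder(
    config$cylinderActivity, config$cylinderVolume,
    config$profile,
    seed = seeds$cylinder, spacing = config$spacing
  )
  factor <- deriveConversionFactor(
    cyl$counts, config$cylinderActivity, config$cylinderVolume,
    config$profile@acquisitionSeconds
  )
  truth <- buildGroundTruth(config$phantom, spacing = config$spacing)
  counts <- simulateAcquisition(truth, config$profile,
    seed = seeds$phantom
  )
  calibrated <- applyCalibration(counts, factor)
  results <- crcAnalysis(calibrated, config$phantom,
    injected = config$injected, weight = config$weight,
    voiScale = config$voiScale, nBackground = config$nBackground,
    backgroundDiameter = config$backgroundDiameter,
    clearance = config$clearance, visibilityK = config$visibilityK
  )
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results, file.path(config$outDir, "crc_results.csv"),
      row.names = FALSE
    )
    jsonlite::write_json(
      c(
        list(kbq_per_count = factor@kbqPerCount, scanner = factor@scanner),
        factor@derivation
      ),
      file.path(config$outDir, "conversion_factor.json"),
      auto_unbox = TRUE, digits = NA
    )
    writeManifest(config$outDir, config, seeds)
  }
  list(factor = factor, results = results, calibrated = calibrated,
    truth = truth
  )
}

#' Run the cohort analysis study
#'
#' Simulates (or ingests) a two-scanner cohort and produces the three
#' clinical-style reports: the per-tissue scanner comparison with its
#' cross-tissue average p-value, the intrapatient liver variability
#' summary, and the longitudinal tumor trajectory report. When
#' `config$outDir` is set, writes `comparison.csv`, `trajectory.csv`,
#' `liver_cohort.csv`, `summary.json` and `manifest.json`.
#'
#' @param config A [pipelineConfig()] list.
#' @param cohortTable Optional tidy cohort `data.frame` (see
#'   [readCohortTable()]); when supplied it replaces the simulated
#'   tissue cohort and liver measurements.
#' @return List with `comparison` (with attribute `averageP`),
#'   `noSignificantDifference` (logical at `config$alpha`),
#'   `variability`, `trajectory`, `reduction` (baseline-to-last percent
#'   reduction, reported) and `tissues` (the cohort actually analyzed).
#' @export
#' @examples
#' res <- runCohortStudy(pipelineConfig(seed = 9))
#' attr(res$comparison, "averageP")
#' res$variability$reportedPercent
runCohortStudy <- function(config = pipelineConfig(), cohortTable = NULL) {
  stopifnot(inherits(config, "qspectConfig"))
  seeds <- list(
    tissues = stageSeed(config$seed, 3L),
    liver = stageSeed(config$seed, 4L)
  )
  spec <- config$cohort
  sim <- simulatePatientCohort(spec, seed = seeds$tissues)
  if (is.null(cohortTable)) {
    tissues <- sim$tissues
    liver <- simulateLiverCohort(
      nPatients = spec@nPatients,
      mean = config$liverMean, sd = config$liverSD,
      seed = seeds$liver
    )
  } else {
    need <- c("patient_id", "scanner", "tissue", "mean_suv")
    miss <- setdiff(need, names(cohortTable))
    if (length(miss)) {
      stop(sprintf(
        "cohort table lacks column(s): %s", paste(miss, collapse = ", ")
      ), call. = FALSE)
    }
    tissues <- data.frame(
      tissue = cohortTable$tissue, scanner = cohortTable$scanner,
      suv = cohortTable$mean_suv
    )
    liver <- cohortTable[cohortTable$tissue == "liver", ]
    liver <- data.frame(
      patient_id = liver$patient_id,
      liver_mean_suv = liver$mean_suv
    )
  }
  scanners <- unique(tissues$scanner)
  if (length(scanners) != 2L) {
    stop("cohort must cover exactly two scanners", call. = FALSE)
  }
  a <- tissues[tissues$scanner == scanners[1], ]
  b <- tissues[tissues$scanner == scanners[2], ]
  comparison <- compareScanners(a, b, exactLimit = config$exactLimit)
  noSig <- !any(comparison$p < config$alpha)

  variability <- if (length(unique(liver$patient_id)) >= 2L ||
    any(table(liver$patient_id) >= 2L)) {
    intrapatientVariability(liver)
  } else {
    warning("fewer than 2 studies per patient: variability stage skipped",
      call. = FALSE
    )
    NULL
  }
  trajectory <- trajectoryReport(sim$series)
  reduction <- percentReduction(sim$series, reported = TRUE)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(comparison, file.path(config$outDir, "comparison.csv"),
      row.names = FALSE
    )
    write.csv(trajectory$table, file.path(config$outDir, "trajectory.csv"),
      row.names = FALSE
    )
    write.csv(liver, file.path(config$outDir, "liver_cohort.csv"),
      row.names = FALSE
    )
    jsonlite::write_json(
      list(
        average_p = attr(comparison, "averageP"),
        no_significant_difference = noSig,
        liver_variability_percent = if (is.null(variability)) {
          NULL
        } else {
          variability$reportedPercent
        },
        tumor_reduction_percent = reduction
      ),
      file.path(config$outDir, "summary.json"),
      auto_unbox = TRUE, digits = NA
    )
    writeManifest(config$outDir, config, seeds)
  }
  list(
    comparison = comparison, noSignificantDifference = noSig,
    variability = variability, trajectory = trajectory,
    reduction = reduction, tissues = tissues
  )
}
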