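## S4 classes for the quantitative SPECT/CT pipeline.

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))

#' ActivityImage: a 3D voxel volume with physical metadata
#'
#' The common currency of every pipeline stage: a 3D scalar grid carrying
#' voxel spacing (mm), a units tag (`"kBq_per_cm3"` for activity
#' concentration, `"counts"` for raw camera counts, `"suv"` for
#' standardized uptake values), a physical origin and, where relevant, the
#' name of the scanner profile that produced it (used to guard against
#' applying a calibration factor across scanners).
#'
#' @slot voxels 3D numeric array.
#' @slot spacing Voxel spacing in mm, one value per axis (x, y, z).
#' @slot units One of `"kBq_per_cm3"`, `"counts"`, `"suv"`.
#' @slot origin Physical coordinate (mm) of the center of voxel (1,1,1).
#' @slot scanner Scanner profile name, or `""` when not applicable.
#' @exportClass ActivityImage
setClass("ActivityImage",
  representation(
    voxels = "array",
    spacing = "numeric",
    units = "character",
    origin = "numeric",
    scanner = "character"
  ),
  prototype(
    spacing = c(4.8, 4.8, 4.8),
    units = "kBq_per_cm3",
    origin = c(0, 0, 0),
    scanner = ""
  )
)

validActivityImage <- function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L) {
    msg <- c(msg, "'voxels' must be a 3D array")
  }
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) {
    msg <- c(msg, "'spacing' must be 3 positive finite values (mm)")
  }
  if (length(object@units) != 1L ||
      !object@units %in% c("kBq_per_cm3", "counts", "suv")) {
    msg <- c(msg, "'units' must be one of kBq_per_cm3, counts, suv")
  }
  if (length(object@origin) != 3L) {
    msg <- c(msg, "'origin' must have length 3")
  }
  if (any(!is.finite(object@voxels))) {
    msg <- c(msg, "voxel values must be finite")
  } else if (identical(object@units, "counts") && any(object@voxels < 0)) {
    msg <- c(msg, "count images cannot contain negative voxels")
  }
  if (length(msg)) msg else TRUE
}
setValidity("ActivityImage", validActivityImage)

#' Construct an ActivityImage
#'
#' @param voxels 3D numeric array.
#' @param spacing Voxel spacing in mm (scalar or length 3).
#' @param units `"kBq_per_cm3"`, `"counts"` or `"suv"`.
#' @param origin Physical position (mm) of the first voxel center.
#' @param scanner Optional scanner profile name.
#' @return An [ActivityImage-class] object.
#' @export
#' @examples
#' img <- ActivityImage(array(1, c(4, 4, 4)), spacing = 4.8)
#' voxelVolume(img) # cm^3
ActivityImage <- function(voxels, spacing = c(4.8, 4.8, 4.8),
                          units = "kBq_per_cm3",
                          origin = NULL, scanner = "") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(origin)) {
    ## center the grid on the physical origin, voxel-center convention
    origin <- -(dim(voxels) - 1) / 2 * spacing
  }
  new("ActivityImage",
    voxels = voxels, spacing = as.numeric(spacing),
    units = units, origin = as.numeric(origin), scanner = scanner
  )
}

#' PhantomSpec: ground-truth phantom geometry and concentrations
#'
#' Describes a fillable body phantom as an elliptical cylinder containing
#' spherical inserts and an optional cold cylindrical lung insert, with
#' known activity concentrations. The default construction (see
#' [nemaPhantomSpec()]) is the NEMA IEC body phantom with six spheres of
#' inner diameter 10-37 mm.
#'
#' @slot bodySemiAxes Interior semi-axes (mm) of the elliptical body
#'   cross-section, (x, y).
#' @slot bodyLength Interior body length (mm) along the scanner axis.
#' @slot spheres `data.frame` with columns `diameter` (inner diameter,
#'   mm), `x`, `y`, `z` (center, mm), `fill_volume` (cm^3, bookkeeping)
#'   and `concentration` (kBq cm^-3).
#' @slot lungInsert Named numeric vector `c(diameter, length,
#'   concentration)` for the central cold cylinder; zero diameter disables
#'   the insert.
#' @slot backgroundConcentration Background water concentration
#'   (kBq cm^-3).
#' @slot totalFillVolume Phantom fill capacity (cm^3, bookkeeping).
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    bodySemiAxes = "numeric",
    bodyLength = "numeric",
    spheres = "data.frame",
    lungInsert = "numeric",
    backgroundConcentration = "numeric",
    totalFillVolume = "numeric"
  )
)

validPhantomSpec <- function(object) {
  msg <- character()
  sp <- object@spheres
  need <- c("diameter", "x", "y", "z", "fill_volume", "concentration")
  if (!all(need %in% names(sp))) {
    return(paste(
      "'spheres' must have columns",
      paste(need, collapse = ", ")
    ))
  }
  if (length(object@bodySemiAxes) != 2L || any(object@bodySemiAxes <= 0)) {
    msg <- c(msg, "'bodySemiAxes' must be 2 positive values (mm)")
  }
  if (object@bodyLength <= 0) {
    msg <- c(msg, "'bodyLength' must be positive")
  }
  if (nrow(sp)) {
    if (any(sp$diameter <= 0)) msg <- c(msg, "sphere diameters must be > 0")
    if (any(sp$concentration < 0)) {
      msg <- c(msg, "sphere concentrations must be >= 0")
    }
    ## pairwise non-overlap
    if (nrow(sp) > 1L) {
      cen <- as.matrix(sp[, c("x", "y", "z")])
      r <- sp$diameter / 2
      for (i in seq_len(nrow(sp) - 1L)) {
        for (j in seq.int(i + 1L, nrow(sp))) {
          d <- sqrt(sum((cen[i, ] - cen[j, ])^2))
          if (d < r[i] + r[j]) {
            msg <- c(msg, sprintf(
              "spheres %d and %d overlap (centers %.1f mm apart)", i, j, d
            ))
          }
        }
      }
    }
    ## spheres inside the body
    a <- object@bodySemiAxes[1]
    b <- object@bodySemiAxes[2]
    e <- sqrt((sp$x / a)^2 + (sp$y / b)^2)
    if (any(e > 1) || any(abs(sp$z) + sp$diameter / 2 > object@bodyLength / 2)) {
      msg <- c(msg, "spheres must lie within the phantom body")
    }
    ## spheres clear of the lung insert
    if (object@lungInsert[["diameter"]] > 0) {
      rl <- object@lungInsert[["diameter"]] / 2
      dxy <- sqrt(sp$x^2 + sp$y^2)
      if (any(dxy < rl + sp$diameter / 2)) {
        msg <- c(msg, "spheres overlap the lung insert")
      }
    }
  }
  if (object@backgroundConcentration < 0) {
    msg <- c(msg, "'backgroundConcentration' must be >= 0")
  }
  if (length(msg)) msg else TRUE
}
setValidity("PhantomSpec", validPhantomSpec)

#' Construct the default NEMA IEC body phantom specification
#'
#' The interior body is modelled as an elliptical cylinder whose length is
#' derived from the stated fill capacity; six fillable spheres (inner
#' diameters 10, 13, 17, 22, 28 and 37 mm, fill volumes 0.5, 1.0, 2.8,
#' 5.8, 11.7 and 29 cm^3) sit on a hexagonal ring of 57 mm radius in the
#' central transverse plane, and a cold 50 mm cylinder at the center
#' stands in for the lung insert. Default concentrations follow a hot
#' sphere : background preparation of 35.4 : 11.0 kBq cm^-3 (about 3.2:1).
#'
#' @param sphereConcentration Hot-sphere activity concentration
#'   (kBq cm^-3); recycled over spheres.
#' @param backgroundConcentration Background concentration (kBq cm^-3).
#' @param sphereDiameters Inner diameters (mm).
#' @param fillVolumes Nominal fill volumes (cm^3), bookkeeping only; the
#'   voxelization uses the inner diameters.
#' @param ringRadius Radius (mm) of the transverse sphere ring.
#' @param capacity Interior fill capacity (cm^3); fixes the body length
#'   given the semi-axes.
#' @param bodySemiAxes Interior semi-axes (mm) of the body cross-section.
#' @param lungDiameter Outer diameter (mm) of the cold lung insert.
#' @return A [PhantomSpec-class] object.
#' @export
#' @examples
#' spec <- nemaPhantomSpec()
#' spec
nemaPhantomSpec <- function(sphereConcentration = 35.4,
                            backgroundConcentration = 11.0,
                            sphereDiameters = c(10, 13, 17, 22, 28, 37),
                            fillVolumes = c(0.5, 1.0, 2.8, 5.8, 11.7, 29),
                            ringRadius = 57,
                            capacity = 9650,
                            bodySemiAxes = c(150, 98),
                            lungDiameter = 50) {
  n <- length(sphereDiameters)
  conc <- rep_len(sphereConcentration, n)
  fills <- rep_len(fillVolumes, n)
  ang <- (seq_len(n) - 1L) * 2 * pi / n
  bodyLength <- capacity * 1000 / (pi * prod(bodySemiAxes))
  spheres <- data.frame(
    diameter = sphereDiameters,
    x = ringRadius * cos(ang),
    y = ringRadius * sin(ang),
    z = 0,
    fill_volume = fills,
    concentration = conc
  )
  new("PhantomSpec",
    bodySemiAxes = bodySemiAxes,
    bodyLength = bodyLength,
    spheres = spheres,
    lungInsert = c(
      diameter = lungDiameter, length = bodyLength,
      concentration = 0
    ),
    backgroundConcentration = backgroundConcentration,
    totalFillVolume = capacity
  )
}

#' ScannerProfile: parametric camera forward model
#'
#' Collapses acquisition and reconstruction into three numbers: an
#' isotropic Gaussian point-spread function (the partial-volume mechanism
#' CRC measures), a counting sensitivity, and an acquisition time; plus a
#' Poisson-noise switch and a multiplicative calibration bias used to
#' stress-test the calibration chain.
#'
#' @slot name Profile label, e.g. `"symbia_lehr"`.
#' @slot psfFwhm Reconstructed-image PSF full width at half maximum (mm).
#' @slot sensitivity Expected counts per (kBq s) of in-voxel activity.
#' @slot acquisitionSeconds Total acquisition time (s).
#' @slot noise Poisson counting noise on/off.
#' @slot calibrationBias Multiplicative count bias (1 = unbiased).
#' @exportClass ScannerProfile
setClass("ScannerProfile",
  representation(
    name = "character",
    psfFwhm = "numeric",
    sensitivity = "numeric",
    acquisitionSeconds = "numeric",
    noise = "logical",
    calibrationBias = "numeric"
  )
)

setValidity("ScannerProfile", function(object) {
  msg <- character()
  if (object@psfFwhm < 0) msg <- c(msg, "'psfFwhm' must be >= 0")
  if (object@sensitivity <= 0) msg <- c(msg, "'sensitivity' must be > 0")
  if (object@acquisitionSeconds <= 0) {
    msg <- c(msg, "'acquisitionSeconds' must be > 0")
  }
  if (object@calibrationBias <= 0) {
    msg <- c(msg, "'calibrationBias' must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a scanner profile
#'
#' `scannerProfile()` builds a profile from explicit parameters;
#' `defaultScannerProfile()` returns one of the two bundled profiles:
#' `"symbia_lehr"` (PSF FWHM 13 mm; low-energy high-resolution
#' collimators) and `"infinia_me"` (PSF FWHM 15 mm; medium-energy
#' collimators). The FWHM values were calibrated by least-squares fit of
#' the noise-free model CRC curve to measured body-phantom recovery
#' curves; see the package vignette. Both profiles use 96 views x 35 s
#' (3360 s total) and a default sensitivity of 0.004 counts per kBq s,
#' which yields a realistic SPECT count density (about 1.6 million counts
#' on the default body phantom).
#'
#' @param name Profile label.
#' @param psfFwhm PSF full width at half maximum (mm).
#' @param sensitivity Counts per (kBq s).
#' @param acquisitionSeconds Total acquisition time (s).
#' @param noise Logical; Poisson counting noise.
#' @param calibrationBias Multiplicative count bias.
#' @return A [ScannerProfile-class] object.
#' @export
#' @examples
#' defaultScannerProfile("symbia_lehr")
scannerProfile <- function(name, psfFwhm, sensitivity = 0.004,
                           acquisitionSeconds = 3360, noise = TRUE,
                           calibrationBias = 1) {
  new("ScannerProfile",
    name = name, psfFwhm = psfFwhm, sensitivity = sensitivity,
    acquisitionSeconds = acquisitionSeconds, noise = noise,
    calibrationBias = calibrationBias
  )
}

#' @rdname scannerProfile
#' @param noiseOn Logical; Poisson noise for the returned default profile.
#' @export
defaultScannerProfile <- function(name = c("symbia_lehr", "infinia_me"),
                                  noiseOn = TRUE) {
  name <- match.arg(name)
  fwhm <- switch(name, symbia_lehr = 13, infinia_me = 15)
  scannerProfile(name, psfFwhm = fwhm, noise = noiseOn)
}

#' CohortSpec: generating parameters for synthetic patient cohorts
#'
#' Holds per-tissue SUV distribution parameters for each scanner (the
#' normal-tissue reference values bundled via [normalTissueReference()]),
#' a longitudinal tumor SUVmax trajectory with liver reference, and the
#' cohort size.
#'
#' @slot tissues `data.frame` with columns `tissue`, `scanner`, `mean`,
#'   `sd`, `n`.
#' @slot nPatients Number of patients for the intrapatient-variability
#'   cohort.
#' @slot tumorTrajectory `data.frame` with columns `week`, `suvmax`,
#'   `scanner`: the noiseless tumor trajectory.
#' @slot tumorNoiseSD Measurement noise SD added to the tumor trajectory.
#' @slot liverReference `c(mean, sd)` of the liver reference uptake for
#'   longitudinal series.
#' @slot seed Default RNG seed for the generators.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    tissues = "data.frame",
    nPatients = "numeric",
    tumorTrajectory = "data.frame",
    tumorNoiseSD = "numeric",
    liverReference = "numeric",
    seed = "numeric"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  ts <- object@tissues
  need <- c("tissue", "scanner", "mean", "sd", "n")
  if (!all(need %in% names(ts))) {
    msg <- c(msg, paste(
      "'tissues' must have columns",
      paste(need, collapse = ", ")
    ))
  } else {
    if (any(ts$sd < 0)) msg <- c(msg, "tissue SDs must be >= 0")
    if (any(ts$n < 1)) msg <- c(msg, "tissue sample sizes must be >= 1")
  }
  if (object@nPatients < 1) msg <- c(msg, "'nPatients' must be >= 1")
  tr <- object@tumorTrajectory
  if (nrow(tr)) {
    if (is.unsorted(tr$week, strictly = TRUE)) {
      msg <- c(msg, "trajectory weeks must be strictly increasing")
    }
    if (any(tr$suvmax < 0)) msg <- c(msg, "trajectory SUVmax must be >= 0")
  }
  if (length(object@liverReference) != 2L || object@liverReference[2] < 0) {
    msg <- c(msg, "'liverReference' must be c(mean, sd) with sd >= 0")
  }
  if (object@tumorNoiseSD < 0) msg <- c(msg, "'tumorNoiseSD' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Reference SUV distributions for normal tissues on two SPECT/CT systems
#'
#' Mean and standard deviation of the mean SUV of nine normal tissues
#' showing physiologic \[I-123\] mIBG uptake (parotid and submandibular
#' glands, left ventricle, liver, adrenals and bladder), with the number
#' of observations per tissue, as measured on a medium-energy-collimator
#' system (`"infinia_me"`) and a low-energy high-resolution system
#' (`"symbia_lehr"`) in a pediatric neuroblastoma population. These are
#' the default generating parameters of the synthetic cohort simulator.
#'
#' @return `data.frame` with columns `tissue`, `scanner`, `mean`, `sd`,
#'   `n`.
#' @export
#' @examples
#' head(normalTissueReference())
normalTissueReference <- function() {
  tissues <- c(
    "r_parotid", "l_parotid", "r_submandibular", "l_submandibular",
    "heart_lv", "liver", "r_adrenal", "l_adrenal", "bladder"
  )
  infinia <- data.frame(
    tissue = tissues, scanner = "infinia_me",
    mean = c(4.4, 4.4, 3.0, 2.8, 2.0, 1.5, 2.0, 1.9, 4.4),
    sd = c(1.5, 1.3, 0.7, 0.6, 0.3, 0.6, 0.3, 0.2, 1.5),
    n = c(16, 16, 19, 19, 33, 39, 14, 6, 35)
  )
  symbia <- data.frame(
    tissue = tissues, scanner = "symbia_lehr",
    mean = c(4.4, 4.4, 3.2, 3.3, 2.0, 1.6, 2.5, 2.4, 4.4),
    sd = c(1.8, 1.6, 1.2, 1.3, 0.8, 0.5, 0.9, 0.9, 1.9),
    n = c(14, 14, 18, 18, 64, 63, 23, 4, 50)
  )
  rbind(infinia, symbia)
}

#' Construct a cohort specification
#'
#' Defaults reproduce the study conditions the synthetic cohorts emulate:
#' the nine-tissue two-scanner reference distributions of
#' [normalTissueReference()], a 28-patient intrapatient-variability
#' cohort, and a 10-point tumor SUVmax trajectory declining from 12.0 to
#' 3.1 over 73 weeks (first four time points on the medium-energy system,
#' the rest on the high-resolution system) with a liver reference of
#' 2.1 +/- 0.2.
#'
#' @param tissues Per-tissue generating parameters (see
#'   [normalTissueReference()]).
#' @param nPatients Patients in the variability cohort.
#' @param tumorTrajectory Noiseless `week`/`suvmax`/`scanner` trajectory.
#' @param tumorNoiseSD Measurement noise SD for observed tumor SUVmax.
#' @param liverReference `c(mean, sd)` liver reference uptake.
#' @param seed Default RNG seed.
#' @return A [CohortSpec-class] object.
#' @export
#' @examples
#' cohortSpec()
cohortSpec <- function(tissues = normalTissueReference(),
                       nPatients = 28,
                       tumorTrajectory = data.frame(
                         week = c(0, 8, 14, 20, 26, 33, 40, 51, 62, 73),
                         suvmax = c(
                           12.0, 11.2, 10.4, 9.6, 8.5,
                           7.2, 6.0, 4.9, 3.9, 3.1
                         ),
                         scanner = rep(
                           c("infinia_me", "symbia_lehr"),
                           c(4, 6)
                         )
                       ),
                       tumorNoiseSD = 0.2,
                       liverReference = c(2.1, 0.2),
                       seed = 20190101) {
  new("CohortSpec",
    tissues = tissues, nPatients = nPatients,
    tumorTrajectory = tumorTrajectory, tumorNoiseSD = tumorNoiseSD,
    liverReference = liverReference, seed = seed
  )
}

#' DoseRecord: syringe assay bookkeeping
#'
#' Pre- and post-injection syringe assays with their timestamps; the net
#' injected activity is the decay-corrected difference (see
#' [netInjectedActivity()]).
#'
#' @slot preActivity Pre-injection assay (kBq).
#' @slot preTime Timestamp of the pre-injection assay.
#' @slot postActivity Residual post-injection assay (kBq).
#' @slot postTime Timestamp of the post-injection assay.
#' @slot injectionTime Injection timestamp.
#' @exportClass DoseRecord
setClass("DoseRecord",
  representation(
    preActivity = "numeric",
    preTime = "POSIXct",
    postActivity = "numeric",
    postTime = "POSIXct",
    injectionTime = "POSIXct"
  )
)

setValidity("DoseRecord", function(object) {
  msg <- character()
  if (object@postActivity < 0) msg <- c(msg, "'postActivity' must be >= 0")
  if (object@preActivity <= object@postActivity) {
    msg <- c(msg, "'preActivity' must exceed 'postActivity'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a dose record
#'
#' @param preActivity Pre-injection syringe assay (kBq).
#' @param postActivity Residual post-injection assay (kBq).
#' @param injectionTime Injection timestamp (`POSIXct`).
#' @param preTime,postTime Assay timestamps; default to `injectionTime`.
#' @return A [DoseRecord-class] object.
#' @export
#' @examples
#' t0 <- as.POSIXct("2015-06-01 09:00", tz = "UTC")
#' doseRecord(170000, 7200, injectionTime = t0)
doseRecord <- function(preActivity, postActivity, injectionTime,
                       preTime = injectionTime, postTime = injectionTime) {
  new("DoseRecord",
    preActivity = preActivity, preTime = as.POSIXct(preTime),
    postActivity = postActivity, postTime = as.POSIXct(postTime),
    injectionTime = as.POSIXct(injectionTime)
  )
}

#' StudyMeta: per-examination metadata
#'
#' @slot weight Patient (or phantom) weight in grams; the SUV denominator.
#' @slot height Height in cm (optional, `NA` when unknown).
#' @slot scanStart Scan start timestamp; the decay-correction target for
#'   SUV normalization.
#' @slot scanner Scanner profile name.
#' @exportClass StudyMeta
setClass("StudyMeta",
  representation(
    weight = "numeric",
    height = "numeric",
    scanStart = "POSIXct",
    scanner = "character"
  )
)

setValidity("StudyMeta", function(object) {
  if (!is.finite(object@weight) || object@weight <= 0) {
    "'weight' must be positive (grams)"
  } else {
    TRUE
  }
})

#' Construct study metadata
#'
#' @param weight Weight in grams.
#' @param scanStart Scan start timestamp.
#' @param scanner Scanner profile name.
#' @param height Height in cm (optional).
#' @return A [StudyMeta-class] object.
#' @export
studyMeta <- function(weight, scanStart, scanner = "", height = NA_real_) {
  new("StudyMeta",
    weight = weight, height = height,
    scanStart = as.POSIXct(scanStart), scanner = scanner
  )
}

#' CalibrationFactor: counts-to-activity conversion
#'
#' The scanner-specific kBq-per-count factor derived from a uniform
#' phantom of known activity and volume, together with its derivation
#' provenance and the count-rate flag (the factor should be derived below
#' 20 kcts/s).
#'
#' @slot kbqPerCount Conversion factor (kBq per count).
#' @slot scanner Scanner profile name the factor belongs to.
#' @slot derivation Named list: `activity` (kBq), `volume` (cm^3),
#'   `totalCounts`, `countRate` (counts/s), `acquisitionSeconds`.
#' @slot rateWarning TRUE when the derivation count rate reached the
#'   20 kcts/s limit.
#' @exportClass CalibrationFactor
setClass("CalibrationFactor",
  representation(
    kbqPerCount = "numeric",
    scanner = "character",
    derivation = "list",
    rateWarning = "logical"
  )
)

setValidity("CalibrationFactor", function(object) {
  if (!is.finite(object@kbqPerCount) || object@kbqPerCount <= 0) {
    "'kbqPerCount' must be positive"
  } else {
    TRUE
  }
})

#' VOI: a volume of interest
#'
#' Either a sphere given by center and diameter (membership =
#' voxel-center-inside-sphere) or an explicit logical voxel mask.
#'
#' @slot label VOI label.
#' @slot center Sphere center (mm), or `NULL` for mask VOIs.
#' @slot diameter Sphere diameter (mm), or `NULL`.
#' @slot mask Logical 3D array, or `NULL` for sphere VOIs.
#' @exportClass VOI
setClass("VOI",
  representation(
    label = "character",
    center = "numericOrNULL",
    diameter = "numericOrNULL",
    mask = "arrayOrNULL"
  )
)

setValidity("VOI", function(object) {
  sphere <- !is.null(object@center)
  if (sphere) {
    if (length(object@center) != 3L) {
      return("sphere VOI 'center' must have length 3")
    }
    if (is.null(object@diameter) || object@diameter <= 0) {
      return("sphere VOI 'diameter' must be > 0")
    }
  } else {
    if (is.null(object@mask)) return("VOI needs a sphere or a mask")
    if (!is.logical(object@mask) || length(dim(object@mask)) != 3L) {
      return("'mask' must be a logical 3D array")
    }
    if (!any(object@mask)) return("mask VOI is empty")
  }
  TRUE
})

#' Construct VOIs
#'
#' @param center Sphere center in physical mm coordinates.
#' @param diameter Sphere diameter (mm).
#' @param label VOI label.
#' @return A [VOI-class] object.
#' @export
#' @examples
#' sphereVOI(c(0, 0, 0), 30, "background")
sphereVOI <- function(center, diameter, label = "voi") {
  new("VOI", label = label, center = as.numeric(center),
      diameter = diameter, mask = NULL)
}

#' @rdname sphereVOI
#' @param mask Logical 3D array aligned with the target image grid.
#' @export
maskVOI <- function(mask, label = "voi") {
  new("VOI", label = label, center = NULL, diameter = NULL, mask = mask)
}

#' LongitudinalSeries: time-ordered tumor SUVmax with liver reference
#'
#' @slot subject Subject identifier.
#' @slot data `data.frame` with columns `week`, `tumor_suvmax`,
#'   `liver_mean_suv`, `scanner`, time-ordered.
#' @exportClass LongitudinalSeries
setClass("LongitudinalSeries",
  representation(subject = "character", data = "data.frame")
)

setValidity("LongitudinalSeries", function(object) {
  d <- object@data
  need <- c("week", "tumor_suvmax", "liver_mean_suv", "scanner")
  if (!all(need %in% names(d))) {
    return(paste("'data' must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(d) && is.unsorted(d$week, strictly = TRUE)) {
    return("'week' must be strictly increasing")
  }
  if (any(d$tumor_suvmax < 0) || any(d$liver_mean_suv < 0)) {
    return("SUV values must be >= 0")
  }
  TRUE
})

#' Construct a longitudinal series
#'
#' @param subject Subject identifier.
#' @param week Time points (weeks), strictly increasing.
#' @param tumorSuvmax Tumor SUVmax at each time point.
#' @param liverMeanSuv Liver reference mean SUV at each time point.
#' @param scanner Scanner profile name per time point.
#' @return A [LongitudinalSeries-class] object.
#' @export
longitudinalSeries <- function(subject, week, tumorSuvmax, liverMeanSuv,
                               scanner) {
  new("LongitudinalSeries",
    subject = subject,
    data = data.frame(
      week = week, tumor_suvmax = tumorSuvmax,
      liver_mean_suv = liverMeanSuv,
      scanner = rep_len(scanner, length(week))
    )
  )
}
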