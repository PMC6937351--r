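## Calibration: decay correction, net injected activity, and the uniform
## phantom kBq-per-count conversion factor.

#' Decay-correct an activity between two times
#'
#' `activity0 * 2^(-(t - t0)/halfLife)`. Back-correction (`t` earlier
#' than `t0`) is permitted and increases the activity.
#'
#' @param activity0 Activity (kBq) assayed at `t0`.
#' @param t0,t Timestamps (`POSIXct`) or numeric times in hours.
#' @param halfLife Isotope half-life in hours; defaults to I-123
#'   ([iodine123HalfLife()]).
#' @return Decay-corrected activity in kBq.
#' @export
#' @examples
#' decayCorrect(370000, 0, 13.2213) # one half-life -> 185000
decayCorrect <- function(activity0, t0, t, halfLife = iodine123HalfLife()) {
  if (!is.numeric(halfLife) || halfLife <= 0) {
    stop("'halfLife' must be positive (hours)", call. = FALSE)
  }
  dt <- if (inherits(t0, "POSIXct") || inherits(t, "POSIXct")) {
    as.numeric(difftime(as.POSIXct(t), as.POSIXct(t0), units = "hours"))
  } else {
    t - t0
  }
  activity0 * 2^(-dt / halfLife)
}

#' Net injected activity from a syringe dose record
#'
#' Both assays are decay-corrected to the injection time before
#' subtracting the residual from the pre-injection activity, so that the
#' result is the activity actually delivered at injection.
#'
#' @param rec A [DoseRecord-class].
#' @param halfLife Isotope half-life in hours.
#' @return Net injected activity (kBq) referenced to the injection time.
#' @export
#' @examples
#' t0 <- as.POSIXct("2015-06-01 09:00", tz = "UTC")
#' netInjectedActivity(doseRecord(170000, 7200, injectionTime = t0))
netInjectedActivity <- function(rec, halfLife = iodine123HalfLife()) {
  stopifnot(is(rec, "DoseRecord"))
  validObject(rec)
  pre <- decayCorrect(rec@preActivity, rec@preTime, rec@injectionTime,
    halfLife = halfLife
  )
  post <- decayCorrect(rec@postActivity, rec@postTime, rec@injectionTime,
    halfLife = halfLife
  )
  net <- pre - post
  if (net <= 0) {
    stop("net injected activity is not positive; check the assays",
      call. = FALSE
    )
  }
  net
}

#' Derive the kBq-per-count conversion factor from a uniform phantom
#'
#' The factor is `activity / totalCounts`, with the total taken over the
#' whole count image (or a phantom mask): the analogue of calibrating a
#' camera against a uniform cylinder of known volume containing a known
#' activity. The derivation count rate is recorded and the factor is
#' flagged (with a warning) when it reaches 20 kcts/s, above which camera
#' dead-time makes the calibration unreliable.
#'
#' @param counts An [ActivityImage-class] with units `"counts"` from a
#'   uniform phantom acquisition.
#' @param activity Known activity in the phantom (kBq).
#' @param volume Known water volume (cm^3); provenance only, the factor
#'   is activity-per-count.
#' @param acquisitionSeconds Acquisition time (s) used for the count
#'   rate.
#' @param mask Optional logical array restricting the count total.
#' @param rateLimit Count-rate warning threshold (counts/s).
#' @return A [CalibrationFactor-class].
#' @seealso [applyCalibration()], [simulateUniformCylinder()]
#' @export
#' @examples
#' prof <- defaultScannerProfile(noiseOn = FALSE)
#' cyl <- simulateUniformCylinder(111000, 6000, prof, spacing = 6)
#' deriveConversionFactor(cyl$counts, 111000, 6000, 3360)
deriveConversionFactor <- function(counts, activity, volume,
                                   acquisitionSeconds,
                                   mask = NULL, rateLimit = 20000) {
  stopifnot(is(counts, "ActivityImage"))
  if (!identical(imageUnits(counts), "counts")) {
    stop("'counts' must be a count image", call. = FALSE)
  }
  if (activity <= 0 || volume <= 0) {
    stop("'activity' and 'volume' must be positive", call. = FALSE)
  }
  if (acquisitionSeconds <= 0) {
    stop("'acquisitionSeconds' must be positive", call. = FALSE)
  }
  v <- voxels(counts)
  total <- if (is.null(mask)) sum(v) else sum(v[mask])
  if (total <= 0) {
    stop("zero total counts: cannot derive a conversion factor",
      call. = FALSE
    )
  }
  rate <- total / acquisitionSeconds
  warn <- rate >= rateLimit
  if (warn) {
    warning(sprintf(
      "derivation count rate %.1f kcts/s reaches the %.0f kcts/s limit",
      rate / 1000, rateLimit / 1000
    ), call. = FALSE)
  }
  new("CalibrationFactor",
    kbqPerCount = activity / total,
    scanner = scannerName(counts),
    derivation = list(
      activity = activity, volume = volume, totalCounts = total,
      countRate = rate, acquisitionSeconds = acquisitionSeconds
    ),
    rateWarning = warn
  )
}

#' Convert a count image to activity concentration
#'
#' Each voxel becomes `counts * kbqPerCount / voxelVolume` (kBq cm^-3).
#' The factor must have been derived on the same scanner profile as the
#' image; a name mismatch is a configuration error.
#'
#' @param counts An [ActivityImage-class] with units `"counts"`.
#' @param factor A [CalibrationFactor-class].
#' @return An [ActivityImage-class] with units `"kBq_per_cm3"`.
#' @export
applyCalibration <- function(counts, factor) {
  stopifnot(is(counts, "ActivityImage"), is(factor, "CalibrationFactor"))
  if (!identical(imageUnits(counts), "counts")) {
    stop("'counts' must be a count image", call. = FALSE)
  }
  imgScanner <- scannerName(counts)
  facScanner <- scannerName(factor)
  if (nzchar(imgScanner) && nzchar(facScanner) &&
      !identical(imgScanner, facScanner)) {
    stop(sprintf(
      "calibration factor from '%s' cannot be applied to a '%s' image",
      facScanner, imgScanner
    ), call. = FALSE)
  }
  conc <- voxels(counts) * factor@kbqPerCount / voxelVolume(counts)
  ActivityImage(conc,
    spacing = spacing(counts), units = "kBq_per_cm3",
    origin = origin(counts), scanner = imgScanner
  )
}
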