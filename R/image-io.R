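## File formats: NIfTI-1 volumes with JSON unit sidecars, YAML phantom
## and scanner specifications, tidy cohort CSV.

sidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read and write activity images as NIfTI-1 with a JSON sidecar
#'
#' Volumes are stored as float32 NIfTI-1 (`.nii` / `.nii.gz`) with the
#' voxel spacing in the header; the units tag and producing scanner name,
#' which NIfTI has no standard slot for, travel in a JSON sidecar next to
#' the image (`foo.nii.gz` -> `foo.json`). Reading a volume without a
#' sidecar defaults the units to `"counts"` with a warning.
#'
#' @param image An [ActivityImage-class].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `writeActivityImage()` returns `path` invisibly;
#'   `readActivityImage()` returns an [ActivityImage-class].
#' @export
writeActivityImage <- function(image, path) {
  stopifnot(is(image, "ActivityImage"))
  nii <- RNifti::asNifti(
    voxels(image),
    list(pixdim = c(-1, spacing(image), 0, 0, 0, 0)),
    datatype = "float"
  )
  RNifti::writeNifti(nii, path)
  side <- list(
    units = imageUnits(image),
    scanner = scannerName(image),
    origin = origin(image)
  )
  jsonlite::write_json(side, sidecarPath(path), auto_unbox = TRUE,
    digits = NA
  )
  invisible(path)
}

#' @rdname writeActivityImage
#' @export
readActivityImage <- function(path) {
  nii <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(nii)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stop("NIfTI header carries non-positive voxel spacing", call. = FALSE)
  }
  side <- sidecarPath(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    units <- meta$units
    scanner <- if (is.null(meta$scanner)) "" else meta$scanner
    orig <- if (is.null(meta$origin)) NULL else as.numeric(meta$origin)
  } else {
    warning("no units sidecar found; assuming 'counts'", call. = FALSE)
    units <- "counts"
    scanner <- ""
    orig <- NULL
  }
  vox <- as.array(nii)
  vox <- array(as.numeric(vox), dim(vox))
  ActivityImage(vox,
    spacing = as.numeric(sp), units = units,
    origin = orig, scanner = scanner
  )
}

#' Read and write phantom specifications as YAML
#'
#' The bundled `nema_iec_default.yaml` (under `inst/extdata`) encodes the
#' default NEMA IEC body phantom of [nemaPhantomSpec()].
#'
#' @param spec A [PhantomSpec-class].
#' @param path YAML file path.
#' @return `readPhantomSpec()` returns a [PhantomSpec-class];
#'   `writePhantomSpec()` returns `path` invisibly.
#' @export
#' @examples
#' path <- system.file("extdata", "nema_iec_default.yaml",
#'   package = "qspect"
#' )
#' readPhantomSpec(path)
writePhantomSpec <- function(spec, path) {
  stopifnot(is(spec, "PhantomSpec"))
  obj <- list(
    body = list(
      semi_axes_mm = spec@bodySemiAxes,
      length_mm = spec@bodyLength
    ),
    spheres = lapply(seq_len(nrow(spec@spheres)), function(i) {
      as.list(spec@spheres[i, ])
    }),
    lung_insert = as.list(spec@lungInsert),
    background_concentration_kbq_cm3 = spec@backgroundConcentration,
    total_fill_volume_cm3 = spec@totalFillVolume
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  obj <- yaml::read_yaml(path)
  spheres <- do.call(rbind, lapply(obj$spheres, as.data.frame))
  new("PhantomSpec",
    bodySemiAxes = as.numeric(obj$body$semi_axes_mm),
    bodyLength = as.numeric(obj$body$length_mm),
    spheres = spheres,
    lungInsert = unlist(obj$lung_insert),
    backgroundConcentration = obj$background_concentration_kbq_cm3,
    totalFillVolume = obj$total_fill_volume_cm3
  )
}

#' Read and write scanner profiles as YAML
#'
#' A profile file holds one or more named profiles; `readScannerProfile()`
#' returns the requested one (or the first).
#'
#' @param profile A [ScannerProfile-class].
#' @param path YAML file path.
#' @param name Profile name to select; default first in the file.
#' @return `readScannerProfile()` returns a [ScannerProfile-class].
#' @export
writeScannerProfile <- function(profile, path) {
  stopifnot(is(profile, "ScannerProfile"))
  obj <- list(profiles = list(list(
    name = profile@name, psf_fwhm_mm = profile@psfFwhm,
    sensitivity = profile@sensitivity,
    acquisition_seconds = profile@acquisitionSeconds,
    noise = profile@noise, calibration_bias = profile@calibrationBias
  )))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeScannerProfile
#' @export
readScannerProfile <- function(path, name = NULL) {
  obj <- yaml::read_yaml(path)
  profs <- obj$profiles
  if (is.null(profs)) stop("no 'profiles' entry in file", call. = FALSE)
  if (!is.null(name)) {
    keep <- vapply(profs, function(p) identical(p$name, name), logical(1))
    if (!any(keep)) {
      stop(sprintf("no profile named '%s' in file", name), call. = FALSE)
    }
    profs <- profs[keep]
  }
  p <- profs[[1]]
  scannerProfile(
    name = p$name, psfFwhm = p$psf_fwhm_mm,
    sensitivity = p$sensitivity,
    acquisitionSeconds = p$acquisition_seconds,
    noise = isTRUE(p$noise), calibrationBias = p$calibration_bias
  )
}

#' Read a tidy cohort table
#'
#' Expects the long format `patient_id, study_date, scanner, tissue,
#' mean_suv, max_suv` (`max_suv` optional). Schema violations report the
#' offending row.
#'
#' @param path CSV file path.
#' @return Validated `data.frame`.
#' @export
readCohortTable <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "study_date", "scanner", "tissue", "mean_suv")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(sprintf(
      "cohort CSV lacks column(s): %s", paste(miss, collapse = ", ")
    ), call. = FALSE)
  }
  bad <- which(!is.finite(d$mean_suv) | d$mean_suv < 0)
  if (length(bad)) {
    stop(sprintf(
      "cohort CSV row %d has an invalid mean_suv", bad[1] + 1L
    ), call. = FALSE)
  }
  d
}

#' Read and write dose records and study metadata as JSON
#'
#' Per-study sidecars: the syringe assays with their timestamps, and the
#' patient weight / scan start used for SUV normalization. Timestamps
#' are stored as ISO-8601 UTC strings.
#'
#' @param rec A [DoseRecord-class].
#' @param path JSON file path.
#' @return The read functions return the reconstructed object; the write
#'   functions return `path` invisibly.
#' @export
writeDoseRecord <- function(rec, path) {
  stopifnot(is(rec, "DoseRecord"))
  fmt <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  jsonlite::write_json(list(
    pre_activity_kbq = rec@preActivity,
    pre_assay_time = fmt(rec@preTime),
    post_activity_kbq = rec@postActivity,
    post_assay_time = fmt(rec@postTime),
    injection_time = fmt(rec@injectionTime)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDoseRecord
#' @export
readDoseRecord <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  ts <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  doseRecord(
    preActivity = o$pre_activity_kbq,
    postActivity = o$post_activity_kbq,
    injectionTime = ts(o$injection_time),
    preTime = ts(o$pre_assay_time),
    postTime = ts(o$post_assay_time)
  )
}

#' @rdname writeDoseRecord
#' @param meta A [StudyMeta-class].
#' @export
writeStudyMeta <- function(meta, path) {
  stopifnot(is(meta, "StudyMeta"))
  jsonlite::write_json(list(
    weight_g = meta@weight,
    height_cm = if (is.na(meta@height)) NULL else meta@height,
    scan_start = format(meta@scanStart, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    scanner = meta@scanner
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDoseRecord
#' @export
readStudyMeta <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  studyMeta(
    weight = o$weight_g,
    scanStart = as.POSIXct(o$scan_start,
      format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"
    ),
    scanner = if (is.null(o$scanner)) "" else o$scanner,
    height = if (length(o$height_cm) != 1L) NA_real_ else
      as.numeric(o$height_cm)
  )
}
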