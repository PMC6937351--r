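## Generics and accessors. Slot access from user code goes through these.

#' Accessors for ActivityImage
#'
#' @param object An [ActivityImage-class].
#' @return `voxels()` the 3D array; `spacing()` the voxel spacing in mm;
#'   `imageUnits()` the units tag; `origin()` the physical coordinate of
#'   the first voxel center; `voxelVolume()` the voxel volume in cm^3;
#'   `scannerName()` the producing scanner profile name.
#' @name ActivityImage-accessors
#' @aliases voxels spacing imageUnits origin voxelVolume scannerName
#' @examples
#' img <- ActivityImage(array(0, c(8, 8, 8)), spacing = 4)
#' spacing(img)
#' voxelVolume(img)
NULL

#' @rdname ActivityImage-accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname ActivityImage-accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @rdname ActivityImage-accessors
#' @export
setGeneric("imageUnits", function(object) standardGeneric("imageUnits"))

#' @rdname ActivityImage-accessors
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))

#' @rdname ActivityImage-accessors
#' @export
setGeneric("voxelVolume", function(object) standardGeneric("voxelVolume"))

#' @rdname ActivityImage-accessors
#' @export
setGeneric("scannerName", function(object) standardGeneric("scannerName"))

#' @rdname ActivityImage-accessors
setMethod("voxels", "ActivityImage", function(object) object@voxels)

#' @rdname ActivityImage-accessors
setMethod("spacing", "ActivityImage", function(object) object@spacing)

#' @rdname ActivityImage-accessors
setMethod("imageUnits", "ActivityImage", function(object) object@units)

#' @rdname ActivityImage-accessors
setMethod("origin", "ActivityImage", function(object) object@origin)

#' @rdname ActivityImage-accessors
setMethod("voxelVolume", "ActivityImage", function(object) {
  prod(object@spacing) / 1000 # mm^3 -> cm^3
})

#' @rdname ActivityImage-accessors
setMethod("scannerName", "ActivityImage", function(object) object@scanner)

#' @rdname ActivityImage-accessors
setMethod("scannerName", "ScannerProfile", function(object) object@name)

#' @rdname ActivityImage-accessors
setMethod("scannerName", "CalibrationFactor", function(object) object@scanner)

setMethod("show", "ActivityImage", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(
    "ActivityImage %d x %d x %d voxels, spacing %s mm, units '%s'%s\n",
    d[1], d[2], d[3],
    paste(format(object@spacing, digits = 3), collapse = " x "),
    object@units,
    if (nzchar(object@scanner)) paste0(", scanner '", object@scanner, "'")
    else ""
  ))
  rng <- range(object@voxels)
  cat(sprintf(
    "  value range [%.4g, %.4g], total %.6g\n",
    rng[1], rng[2], sum(object@voxels)
  ))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: elliptical body %g x %g mm semi-axes, length %.1f mm\n",
    object@bodySemiAxes[1], object@bodySemiAxes[2], object@bodyLength
  ))
  cat(sprintf(
    "  background %.1f kBq/cm^3, capacity %.0f cm^3\n",
    object@backgroundConcentration, object@totalFillVolume
  ))
  if (object@lungInsert[["diameter"]] > 0) {
    cat(sprintf(
      "  lung insert: %.0f mm diameter, concentration %.1f kBq/cm^3\n",
      object@lungInsert[["diameter"]], object@lungInsert[["concentration"]]
    ))
  }
  cat(sprintf("  %d spheres:\n", nrow(object@spheres)))
  print(object@spheres, row.names = FALSE)
})

setMethod("show", "ScannerProfile", function(object) {
  cat(sprintf(
    paste0(
      "ScannerProfile '%s': PSF FWHM %.1f mm, sensitivity %.4g cts/(kBq s),",
      " %g s, noise %s, bias %.3f\n"
    ),
    object@name, object@psfFwhm, object@sensitivity,
    object@acquisitionSeconds, if (object@noise) "on" else "off",
    object@calibrationBias
  ))
})

setMethod("show", "CalibrationFactor", function(object) {
  cat(sprintf(
    "CalibrationFactor: %.6g kBq/count (scanner '%s')\n",
    object@kbqPerCount, object@scanner
  ))
  d <- object@derivation
  cat(sprintf(
    "  derived from %.6g kBq in %.6g cm^3, %.6g counts, %.3g kcts/s%s\n",
    d$activity, d$volume, d$totalCounts, d$countRate / 1000,
    if (object@rateWarning) " [count-rate limit exceeded]" else ""
  ))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d tissue/scanner distributions, %d patients, %d-point tumor trajectory\n",
    nrow(object@tissues), object@nPatients, nrow(object@tumorTrajectory)
  ))
})

setMethod("show", "DoseRecord", function(object) {
  cat(sprintf(
    "DoseRecord: pre %.1f kBq, post %.1f kBq, injection %s\n",
    object@preActivity, object@postActivity,
    format(object@injectionTime)
  ))
})

setMethod("show", "VOI", function(object) {
  if (!is.null(object@center)) {
    cat(sprintf(
      "VOI '%s': sphere d=%.1f mm at (%.1f, %.1f, %.1f) mm\n",
      object@label, object@diameter,
      object@center[1], object@center[2], object@center[3]
    ))
  } else {
    cat(sprintf(
      "VOI '%s': mask with %d voxels\n", object@label, sum(object@mask)
    ))
  }
})

setMethod("show", "LongitudinalSeries", function(object) {
  cat(sprintf(
    "LongitudinalSeries '%s': %d time points, weeks %g-%g\n",
    object@subject, nrow(object@data),
    min(object@data$week), max(object@data$week)
  ))
})

#' Extract the data table of a longitudinal series
#'
#' @param object A [LongitudinalSeries-class].
#' @return `data.frame` with columns `week`, `tumor_suvmax`,
#'   `liver_mean_suv`, `scanner`.
#' @export
setGeneric("seriesData", function(object) standardGeneric("seriesData"))

#' @rdname seriesData
setMethod("seriesData", "LongitudinalSeries", function(object) object@data)
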