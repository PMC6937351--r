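## SUV, CRC and partial-volume-corrected activity recovery.

#' Measure mean, max and voxel count over a VOI
#'
#' Sphere VOIs use the voxel-center-inside-sphere membership rule; mask
#' VOIs use the mask as-is. A sphere that extends beyond the image grid
#' or captures no voxel center is an error.
#'
#' @param image An [ActivityImage-class].
#' @param voi A [VOI-class].
#' @return A list with elements `mean`, `max` and `nVoxels`.
#' @export
#' @examples
#' img <- ActivityImage(array(2, c(16, 16, 16)), spacing = 4)
#' measureVOI(img, sphereVOI(c(0, 0, 0), 20))
measureVOI <- function(image, voi) {
  stopifnot(is(image, "ActivityImage"), is(voi, "VOI"))
  validObject(voi)
  v <- voxels(image)
  if (!is.null(voi@center)) {
    sp <- spacing(image)
    o <- origin(image)
    d <- dim(v)
    r <- voi@diameter / 2
    lastCenter <- o + (d - 1) * sp
    if (any(voi@center - r < o - sp / 2) ||
        any(voi@center + r > lastCenter + sp / 2)) {
      stop(sprintf("VOI '%s' extends beyond the image grid", voi@label),
        call. = FALSE
      )
    }
    gx <- o[1] + (seq_len(d[1]) - 1) * sp[1]
    gy <- o[2] + (seq_len(d[2]) - 1) * sp[2]
    gz <- o[3] + (seq_len(d[3]) - 1) * sp[3]
    member <- squaredDistanceArray(gx, gy, gz, voi@center) <= r^2
  } else {
    if (!identical(dim(voi@mask), dim(v))) {
      stop("mask VOI dimensions do not match the image", call. = FALSE)
    }
    member <- voi@mask
  }
  n <- sum(member)
  if (n == 0L) {
    stop(sprintf("VOI '%s' contains no voxel centers", voi@label),
      call. = FALSE
    )
  }
  vals <- v[member]
  list(mean = mean(vals), max = max(vals), nVoxels = n)
}

#' Standardized uptake value
#'
#' `SUV = Av / (A / w)`: the measured activity concentration divided by
#' the decay-corrected injected activity per unit body weight. With `Av`
#' in kBq cm^-3, `A` in kBq and `w` in grams, the result carries g cm^-3
#' in a phantom; in tissue (density 1 g cm^-3) it is conventionally
#' unitless.
#'
#' @param av Activity concentration (kBq cm^-3); vectorized.
#' @param injected Net injected activity (kBq), decay-corrected to the
#'   scan start.
#' @param weight Body (or phantom) weight in grams.
#' @return SUV value(s).
#' @export
#' @examples
#' computeSUV(35.4, injected = 106200, weight = 16000)
computeSUV <- function(av, injected, weight) {
  if (!is.numeric(injected) || injected <= 0) {
    stop("'injected' must be positive (kBq)", call. = FALSE)
  }
  if (!is.numeric(weight) || weight <= 0) {
    stop("'weight' must be positive (g)", call. = FALSE)
  }
  av * weight / injected
}

#' Contrast recovery coefficient
#'
#' `CRC = (SUVsphere/SUVbkgd - 1) / (Asphere/Abkgd - 1)`: the fraction of
#' the true sphere-to-background contrast recovered in the image. Equal
#' true concentrations leave the CRC undefined.
#'
#' @param suvSphere,suvBkgd Measured sphere and background SUV (same
#'   convention, e.g. VOI means).
#' @param aSphere,aBkgd True sphere and background activity
#'   concentrations (kBq cm^-3).
#' @return The CRC (dimensionless); 1 is perfect recovery.
#' @export
#' @examples
#' computeCRC(2.0, 1.0, 35.4, 11.0)
computeCRC <- function(suvSphere, suvBkgd, aSphere, aBkgd) {
  if (any(suvBkgd <= 0)) {
    stop("background SUV must be positive", call. = FALSE)
  }
  if (any(aBkgd <= 0)) {
    stop("background concentration must be positive", call. = FALSE)
  }
  ratioTrue <- aSphere / aBkgd
  if (any(abs(ratioTrue - 1) < .Machine$double.eps^0.5)) {
    stop("sphere and background concentrations are equal: contrast undefined",
      call. = FALSE
    )
  }
  (suvSphere / suvBkgd - 1) / (ratioTrue - 1)
}

#' Partial-volume-corrected recovered activity concentration
#'
#' Inverts the SUV equation and corrects for the `1 - CRC` count loss of
#' a resolution-limited system:
#' `Av = SUV * (A/w) * [1 + (1 - CRC)]`. At CRC = 1 this reduces to the
#' plain SUV inversion; CRC values above 1 (possible with noise) are
#' passed through with a warning rather than clamped.
#'
#' @param suv Measured SUV.
#' @param injected Net injected activity (kBq).
#' @param weight Weight in grams.
#' @param crc Contrast recovery coefficient; must be >= 0.
#' @return Recovered activity concentration (kBq cm^-3).
#' @export
#' @examples
#' recoverActivity(2, injected = 1000, weight = 1000, crc = 0.5) # 3.0
recoverActivity <- function(suv, injected, weight, crc) {
  if (!is.numeric(injected) || injected <= 0) {
    stop("'injected' must be positive (kBq)", call. = FALSE)
  }
  if (!is.numeric(weight) || weight <= 0) {
    stop("'weight' must be positive (g)", call. = FALSE)
  }
  if (any(crc < 0)) {
    stop("'crc' must be >= 0", call. = FALSE)
  }
  if (any(crc > 1 + 1e-9)) {
    warning("CRC above 1 passed through without clamping", call. = FALSE)
  }
  suv * (injected / weight) * (1 + (1 - crc))
}

#' Percent error of a measured against an actual concentration
#'
#' `100 * (measured/actual - 1)`; positive values are overestimates.
#' `reported = TRUE` rounds half away from zero to integer percent, the
#' convention used on all report surfaces.
#'
#' @param measured,actual Measured and true values; `actual` must be
#'   positive. Vectorized.
#' @param reported Round to the nearest integer percent.
#' @return Percent error.
#' @export
#' @examples
#' percentError(33.5, 35.4) # -5.37
#' percentError(33.5, 35.4, reported = TRUE) # -5
percentError <- function(measured, actual, reported = FALSE) {
  if (any(!is.finite(actual)) || any(actual <= 0)) {
    stop("'actual' must be positive", call. = FALSE)
  }
  err <- 100 * (measured / actual - 1)
  if (reported) roundHalfAway(err) else err
}
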