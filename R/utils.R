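## Internal helpers: constants, seeded evaluation, Gaussian blurring.

#' Physical half-life of I-123
#'
#' Returns the I-123 half-life in hours used by all decay corrections.
#' The value can be overridden for other isotopes via
#' `options(qspect.half_life_h = ...)` or per call through the `halfLife`
#' argument of the calibration functions.
#'
#' @return Half-life in hours (default 13.2213).
#' @export
#' @examples
#' iodine123HalfLife()
iodine123HalfLife <- function() {
  getOption("qspect.half_life_h", 13.2213)
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG
## state afterwards. seed = NULL leaves the RNG stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite integer", call. = FALSE)
  }
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## Deterministic fan-out of one user seed into per-stage seeds. Kept well
## below 2^31 so it is always a valid R integer seed.
stageSeed <- function(seed, stage) {
  if (is.null(seed)) {
    return(NULL)
  }
  (as.numeric(seed) + 104729 * as.numeric(stage)) %% 2147483647
}

## Round half away from zero to the nearest integer, the convention used
## for all integer-percent report surfaces.
roundHalfAway <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

## ---------------------------------------------------------------------
## Separable 3D Gaussian convolution.
##
## The kernel is sampled at voxel centers, truncated at 4 sigma, and
## renormalized to sum exactly to one, so that total counts of objects
## fully interior to the grid are conserved. Edges are zero-padded
## (no kernel renormalization at the boundary).

gaussianKernel1D <- function(sigmaVox) {
  h <- max(1L, as.integer(ceiling(4 * sigmaVox)))
  k <- dnorm(seq.int(-h, h), sd = sigmaVox)
  k / sum(k)
}

## Convolve along one axis by dense banded-matrix multiplication; the
## grids here are small (<= a few hundred per axis) so BLAS wins over
## explicit loops.
convolveAxis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  h <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (off in seq.int(-h, h)) {
    idx <- which(col(K) - row(K) == off)
    K[idx] <- kernel[off + h + 1L]
  }
  perm <- c(axis, setdiff(seq_len(3L), axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  m <- K %*% m
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

gaussianBlur3D <- function(arr, sigmaMM, spacing) {
  if (sigmaMM <= 0) {
    return(arr)
  }
  for (axis in 1:3) {
    sVox <- sigmaMM / spacing[axis]
    arr <- convolveAxis(arr, gaussianKernel1D(sVox), axis)
  }
  arr
}

fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
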