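## Shared fixtures: all built in code at test time.

## noise-free profile, optionally with a perfect (delta) PSF
noiseFreeProfile <- function(psfFwhm = 0, name = "symbia_lehr",
                             bias = 1) {
  scannerProfile(name,
    psfFwhm = psfFwhm, noise = FALSE,
    calibrationBias = bias
  )
}

## default phantom voxelized once per test file at moderate resolution
tinyPhantomTruth <- local({
  cache <- NULL
  function(spacing = 6) {
    if (is.null(cache)) {
      cache <<- buildGroundTruth(nemaPhantomSpec(), spacing = spacing)
    }
    cache
  }
})

## independent U statistic by pair counting (oracle, not rank sums)
pairCountU <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

## independent exact two-tailed p by full enumeration with pair counting
enumerationP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  N <- length(pooled)
  mu <- n1 * (N - n1) / 2
  sets <- utils::combn(N, n1)
  us <- apply(sets, 2, function(idx) {
    pairCountU(pooled[idx], pooled[-idx])
  })
  uObs <- pairCountU(x, y)
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-9)
}
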