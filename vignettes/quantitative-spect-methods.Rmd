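---
title: "Quantitative SPECT/CT: models, calibration and design choices"
author: "qspect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative SPECT/CT: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qspect)
```

## The problem

Single-photon emission tomography has historically been treated as a
qualitative modality. With CT-based attenuation correction and modern
reconstruction it can be made quantitative: voxel values are converted
to activity concentration (kBq cm^-3^) through a scanner-specific
conversion factor, and tissue uptake is normalized to a standardized
uptake value (SUV) exactly as in PET,

$$\mathrm{SUV} = \frac{A_v}{A / w},$$

where $A_v$ is the activity concentration measured in a volume of
interest, $A$ the decay-corrected net injected activity and $w$ the
body weight. For objects comparable in size to the system resolution,
partial-volume losses depress the measured contrast; the fraction of
true contrast recovered is the contrast recovery coefficient

$$\mathrm{CRC} =
  \frac{\mathrm{SUV}_{\mathrm{sphere}}/\mathrm{SUV}_{\mathrm{bkgd}} - 1}
       {A_{\mathrm{sphere}}/A_{\mathrm{bkgd}} - 1},$$

measured on a body phantom with fillable spheres of known
concentration, and the measured concentration can then be corrected for
the $1-\mathrm{CRC}$ count loss,

$$A_v^{\mathrm{corr}} = \mathrm{SUV}\cdot\frac{A}{w}\cdot
  \bigl[1 + (1 - \mathrm{CRC})\bigr].$$

qspect implements this chain end to end — phantom ground truth, a
parametric camera model, uniform-phantom calibration, VOI quantitation,
and the cohort statistics used to compare scanners and track tumor
response — so that every stage can be validated on synthetic data with
known truth.

## The forward model and what it replaces

Clinical quantitative SPECT images come from iterative reconstruction
(OSEM) with collimator-detector response modelling, Monte Carlo scatter
compensation and CT attenuation correction. qspect deliberately does
not simulate projections or photon transport. Instead it works in the
reconstructed-image domain with a two-parameter camera model:

1. an isotropic Gaussian point-spread function (PSF) applied to the
   ground-truth concentration volume — the mechanism that produces
   partial-volume loss, which is what CRC measures; and
2. Poisson counting on the expected counts per voxel,
   `sensitivity x acquisition time x voxel volume x concentration`.

This preserves the phenomenology that the quantitation stages care
about (resolution-dependent contrast loss, count-limited noise,
calibration-factor scaling) at desk scale. What it does *not* emulate:
attenuation and scatter gradients, septal penetration of high-energy
I-123 emissions, reconstruction-correlated noise texture, and
registration error between image and geometry. Conclusions from the
synthetic tests therefore validate the *analysis* chain, not any
particular scanner's physics.

## Phantom geometry

The body phantom is an elliptical cylinder (default interior semi-axes
150 x 98 mm) whose length is derived from the stated fill capacity
(9650 cm^3^, giving 209 mm), with six fillable spheres (inner diameters
10, 13, 17, 22, 28, 37 mm) on a hexagonal ring of 57 mm radius in the
central transverse plane and a cold 50 mm cylinder at the center
standing in for the lung insert. Default concentrations are
35.4 kBq cm^-3^ in the spheres over an 11.0 kBq cm^-3^ background
(3.2:1), the classic hot-sphere preparation from a 106.2 MBq /
3000 cm^3^ stock. Attenuation itself is not modelled (the forward model
lives in the corrected-image domain), so the lung insert is simply
zero-activity.

Voxelization assigns boundary voxels by sub-voxel volume fraction:
spheres via exact distance shells with 4^3^-point supersampling of
shell voxels, cylinders via a separable product of a supersampled 2D
cross-section fraction and an exact 1D axial overlap. Integrated
activity matches the analytic geometry integral to well under 1% at the
default 4.8 mm spacing (a 128-style matrix over a ~60 cm field of
view).

## Calibration

The counts-to-concentration conversion factor is derived as
`activity / total counts` from a uniform cylinder of known activity and
volume (default 111 MBq in 6000 cm^3^), mirroring the
known-volume/known-activity recipe used in practice; deriving it from
the count *total* rather than a per-voxel regression makes it robust to
noise. The derivation count rate is recorded and flagged at the
20 kcts s^-1^ dead-time limit. Decay corrections use a half-life of
13.2213 h (I-123), stored as a package option rather than hard-coded;
net injected activity decay-corrects both syringe assays to the
injection time before subtracting — the physically consistent
bookkeeping where the recorded assay times differ from the injection
time.

## VOI measurement and the sphere-amplitude estimator

`measureVOI()` uses the plain voxel-center-inside-shape membership rule
and reports mean, max and voxel count. For the sphere-insert analysis
this plain mean has a confound: at 4.8 mm voxels even a perfectly
resolved sphere is diluted by boundary voxels whose centers are inside
but whose volumes are not, so a "perfect camera" would not report
CRC = 1. `crcAnalysis()` therefore estimates the sphere amplitude by
weighted least squares over all voxels overlapping the sphere, using
the known sub-voxel overlap fractions $w_i$ and the measured
background $B$:

$$v_i = S\,w_i + B\,(1 - w_i)
\quad\Rightarrow\quad
\hat S = \frac{\sum_i w_i\,(v_i - B(1 - w_i))}{\sum_i w_i^2}.$$

For an unblurred, noise-free volume this recovers the sphere
concentration exactly, so CRC isolates genuine resolution loss from
voxel-discretization artifacts. The background is the mean of the means
of twelve 30 mm spherical VOIs placed with at least 25 mm clearance
from every insert surface and the body wall (mid-plane positions are
preferred; a small set of axial offsets is searched when the mid-plane
cannot host the requested count, and fewer than three placeable VOIs is
a geometry error).

A sphere is reported *visible* when its measured mean exceeds the
background mean by more than two background standard deviations, the SD
being the pooled voxel SD inside the background VOIs — i.e. the
measured noise level of a background-sized structure. (Using the SD of
the twelve VOI means instead would make every sphere "visible" at any
realistic count level, because a 30 mm mean averages noise away far
faster than a 10 mm sphere signal decays.) Invisible spheres stay in
the report but are excluded from CRC and recovery, mirroring phantom
practice where the smallest spheres cannot be resolved. CRC values
above 1 — possible under noise — are warned about, never clamped.

## Default scanner parameters and how they were chosen

| parameter | default | rationale |
|---|---|---|
| PSF FWHM, `symbia_lehr` | 13 mm | least-squares fit of the noise-free model CRC curve (spheres >= 17 mm) to measured body-phantom recovery curves for this scanner class |
| PSF FWHM, `infinia_me` | 15 mm | +2 mm for medium-energy collimation |
| sensitivity | 0.004 cts/(kBq s) | ~1.6M counts per phantom study — a realistic clinical count density at which the 10 mm sphere sits near or below the visibility threshold |
| acquisition time | 3360 s | 96 views x 35 s/stop |
| voxel spacing | 4.8 mm | 128-type matrix over a ~60 cm FOV |
| visibility rule | mean > bkgd + 2 SD | conventional detectability threshold; exposed as `visibilityK` |
| background VOIs | 12 x 30 mm, 25 mm clearance | configurable in `crcAnalysis()` |
| sphere VOI | full inner diameter | deterministic and reproducible; `voiScale` allows concentric sub-VOIs |

With these defaults the noise-free model CRC curve for the visible
spheres is approximately 0.42 / 0.54 / 0.63 / 0.73 (17-37 mm) and the
CRC-corrected recovery errors stay within a few percent for spheres
>= 22 mm and under 10% at 17 mm — the behaviour the acceptance tests
verify over repeated noise realizations.

## Cohort statistics

Scanner comparison uses a two-tailed Mann-Whitney U test implemented
from first principles: U from midranks; an exact two-tailed p by full
enumeration of all $\binom{n_1+n_2}{n_1}$ labelings when
$n_1+n_2 \le 12$ (the permutation distribution of U is symmetric about
$n_1 n_2/2$ under rank reversal, including with ties, so the two-tailed
p is the probability of an at-least-as-large deviation); otherwise a
normal approximation with tie-corrected variance and continuity
correction. The exact path is cross-checked in the test suite against
an independent pair-counting enumeration and against
`stats::wilcox.test()`. Ties are handled by midranks throughout. The
exact/approximate switch at combined n = 12 is configurable.

Other conventions, chosen where the design was genuinely open:

- Quartiles use linear interpolation (type 7); whiskers reach the most
  extreme values within 1.5 IQR of the quartiles, points beyond are
  outliers.
- The intrapatient variability figure is
  `100 x min/max` of the per-patient mean liver SUVs; "variance of the
  mean" is interpreted as the variance across per-patient means (the
  alternative — a squared standard error — would be an order of
  magnitude smaller and is not what a between-patient variability
  summary needs).
- Report surfaces round percents to the nearest integer, half away
  from zero; p-values print to 3 decimals.
- No multiple-testing correction is applied across the nine tissues,
  matching standard practice for this kind of descriptive comparison.
  A consequence worth knowing: under a pure null with nine uncorrected
  tests of size ~0.05, the chance that *all nine* are non-significant
  is only about $0.96^8 \approx 0.7$, so "no significant tissue" is
  the typical but not the near-certain outcome of a null comparison.

## What the synthetic cohorts emulate — and what they do not

`simulatePatientCohort()` draws per-tissue mean SUVs from
truncated-at-zero normals with the bundled two-scanner reference
parameters (nine normal tissues; e.g. liver 1.6 +/- 0.5, parotid
4.4 +/- 1.8), and a ten-point tumor SUVmax trajectory declining from
12.0 to 3.1 over 73 weeks with a 2.1 +/- 0.2 liver reference.
`simulateLiverCohort()` generates the serial-imaging cohort (28
patients, 2-10 studies each, alternating scanners). Draws are
independent within and across patients: there is no between-patient
random effect, no within-patient correlation, and no scanner bias
unless configured. Consequently the simulated min/max ratio of
per-patient liver means concentrates around 40-55% rather than the
extreme spread a real heterogeneous cohort can show, and parameter
recovery — not reproduction of any particular clinical summary — is
the property the tests assert.

## Numerical choices

- Gaussian kernels are sampled at voxel centers, truncated at
  4 sigma and renormalized to unit sum, so blurring conserves the
  total counts of interior objects to <0.1%; convolution is separable
  and implemented as banded-matrix products per axis.
- Boundary supersampling is 4 points per axis (64 per voxel; 8 for the
  calibration cylinder's 2D cross-section), comfortably above the
  8-subvoxel minimum needed to stabilize VOI means at 4.8 mm spacing.
- Simulations take a single integer seed; Poisson sampling is the only
  stochastic element, the caller's RNG state is saved and restored,
  and pipeline runs fan one global seed out to per-stage seeds by a
  fixed additive rule, recorded in the run manifest.
- Degenerate inputs fail loudly: overlapping spheres, non-positive
  spacing/activity/volume/weight, equal sphere and background
  concentrations (undefined contrast), empty VOIs, cross-scanner
  calibration factors.

## Problem sizes used in the validation suite

The test suite and the acceptance script run the full phantom chain at
4.8 mm spacing (~200k voxels) over ten noise seeds, the cohort
analysis at the bundled reference sample sizes, the null calibration of
the rank test over 2000 simulated cohorts, and 200 replicate null
cohort pairs for the family-wise behaviour. These sizes were chosen so
the whole suite runs in well under a minute on a laptop-class machine
while keeping Monte Carlo error comfortably inside the asserted
tolerances.

## Known limitations

- The forward model omits attenuation, scatter and reconstruction
  noise correlations; CRC values are calibrated to a realistic range
  but are not predictions for any specific scanner.
- The visibility rule is a simple mean-plus-2-SD threshold on one VOI
  statistic, not an observer model; near-threshold spheres flicker in
  and out across noise realizations, with a selection bias on their
  conditional CRC.
- SUV conventions: phantom SUV carries g cm^-3^; tissue SUV is treated
  as unitless (tissue density 1 g cm^-3^).
- The longitudinal module tracks SUVmax against a liver reference; it
  does not segment tumors or measure lesion size.
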