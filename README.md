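# qspect

Quantitative SPECT/CT analysis for single-photon radiotracers such as
[I-123] mIBG: phantom-based calibration of count images to activity
concentration, standardized uptake values (SUV), contrast recovery
coefficients (CRC) with partial-volume-corrected activity recovery, and
the nonparametric cohort statistics used to compare scanners, quantify
intrapatient variability and track longitudinal tumor response. A
parametric simulator (voxelized NEMA-IEC-style phantoms, Gaussian PSF,
Poisson counting) provides ground truth, so the whole chain is testable
without clinical data.

It is aimed at physicists and imaging scientists who want a reproducible,
scriptable reference implementation of the quantitative-SPECT analysis
chain — for method development, teaching, or validating site-specific
workflows — rather than at clinical reporting.

## The model

Three equations drive everything. Tissue uptake is normalized to the
decay-corrected net injected activity `A` (kBq) and body weight `w` (g):

    SUV = Av / (A / w)

where `Av` is the activity concentration (kBq/cm^3) measured in a VOI.
On a hot-sphere phantom with known sphere and background concentrations
`A_sphere`, `A_bkgd`, the recovered fraction of true contrast is

    CRC = (SUV_sphere / SUV_bkgd - 1) / (A_sphere / A_bkgd - 1)

and the partial-volume-corrected concentration estimate is

    Av_corr = SUV * (A / w) * [1 + (1 - CRC)].

The camera is modelled in the reconstructed-image domain as an isotropic
Gaussian PSF followed by Poisson counting; the counts-to-kBq conversion
factor is derived from a uniform cylinder of known activity and volume,
as in clinical practice. See the vignette
(`vignettes/quantitative-spect-methods.Rmd`) for the full account of the
model, parameter defaults and design choices.

## Worked example

Simulate the default body phantom (spheres 35.4 kBq/cm^3 over an
11.0 kBq/cm^3 background), calibrate against a 111 MBq / 6000 cm^3
uniform cylinder, and run the sphere-by-sphere accuracy analysis:

```r
library(qspect)
study <- runPhantomStudy(pipelineConfig(seed = 3))
study$results[, c("label", "visible", "crc", "recovered_kbq_cm3",
                  "reported_percent_error")]
#>         label visible       crc recovered_kbq_cm3 reported_percent_error
#> 1 sphere_10mm   FALSE        NA                NA                     NA
#> 2 sphere_13mm    TRUE 0.2883391          30.76744                    -13
#> 3 sphere_17mm    TRUE 0.3989309          33.08548                     -7
#> 4 sphere_22mm    TRUE 0.5110577          34.82840                     -2
#> 5 sphere_28mm    TRUE 0.6310654          36.01636                      2
#> 6 sphere_37mm    TRUE 0.7354593          36.48006                      3
#> 7  background    TRUE 1.0000000          10.96324                      0
```

Reading: at this noise level the 10 mm sphere fails the visibility rule
(its VOI mean does not exceed background + 2 SD); CRC rises
monotonically with sphere size as partial-volume loss shrinks; and after
CRC correction the recovered concentrations agree with the true
35.4 kBq/cm^3 within ±10% for all spheres of 17 mm and larger, with the
background recovered to within 1%.

The cohort side simulates two-scanner normal-tissue SUV samples,
compares them tissue by tissue with a two-tailed Mann-Whitney U test,
and summarizes liver variability and tumor response:

```r
res <- runCohortStudy(pipelineConfig(seed = 3))
round(attr(res$comparison, "averageP"), 3)
#> [1] 0.517
sum(res$comparison$significant)
#> [1] 0
res$reduction   # % SUVmax reduction, baseline -> last time point
#> [1] 77
```

A thin command-line interface over the same functions is installed at
`inst/scripts/qspect.R`
(`Rscript inst/scripts/qspect.R run-phantom-study --seed 3 --out DIR`,
plus `simulate-phantom`, `calibrate`, `apply-cal`, `suv`, `crc`,
`compare`, `run-cohort-study`).

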