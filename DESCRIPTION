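Package: qspect
Title: Quantitative SPECT/CT Phantom Calibration, SUV Quantitation and
    Cohort Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative single-photon emission computed
    tomography (SPECT/CT) analysis with [I-123] mIBG and similar
    radiotracers. Provides phantom-based calibration of count images to
    activity concentration via a uniform-cylinder conversion factor,
    standardized uptake value (SUV) computation from decay-corrected net
    injected activity and body weight, contrast recovery coefficient
    (CRC) measurement on the NEMA IEC body phantom with partial-volume
    corrected activity recovery, and the nonparametric cohort statistics
    used to compare scanners, quantify intrapatient variability and track
    longitudinal tumor response. A parametric simulator (voxelized
    phantoms, Gaussian point-spread blurring, Poisson counting) generates
    ground-truth and degraded volumes so the full pipeline can be
    exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
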