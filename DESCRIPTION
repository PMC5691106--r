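Package: petdyntex
Title: Dual-Time-Point FDG-PET Tumor Texture Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying intratumoral heterogeneity on paired
    (standard and delayed) 18F-FDG PET acquisitions. Implements
    decay-corrected SUV computation, semi-automatic tumor delineation by a
    fixed-fraction SUVmax threshold inside a user box with necrosis
    accounting and hottest-lesion selection, SUV and volume metrics
    (SUVmax, SUVmean, SUVpeak, MTV, TLG), eighteen three-dimensional
    textural features from 16-level gray-level co-occurrence and run-length
    matrices plus gradient-based energies, paired cohort statistics with
    automatic parametric/non-parametric test selection, and a seeded
    synthetic phantom generator for paired dual-time-point cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
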