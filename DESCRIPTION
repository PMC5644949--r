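Package: somnostat
Title: Quantifying Sleep Homeostasis from Hypnograms, EEG Spectra, and
    Imaging Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style toolkit for quantifying homeostatic sleep
    need. Implements vigilance-state bookkeeping from epoch-scored
    hypnograms (hourly state times, baseline-relative accumulated
    rebound curves, first-NREM-episode detection, transition-epoch
    masking), EEG spectral analysis (Hann-taper power spectra at 0.25 Hz
    resolution, band power, vigilance-state-weighted total-power
    normalization, and the equal-NREM-epoch delta-power time course with
    outlier screening), PET region-of-interest mGluR5 availability
    ratios (DV_norm), CRLB-gated magnetic-resonance-spectroscopy
    metabolite tables, Y-maze spontaneous-alternation and habituation
    scoring, and the correlation and multiplicity-control inference
    layer that connects these markers. A bundled synthetic-data
    generator produces mouse sleep-deprivation recordings driven by a
    two-process (Process S) sleep-pressure model, human two-condition
    imaging cohorts with planted correlations, and Y-maze entry
    sequences, so every stage of the pipeline can be exercised against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
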