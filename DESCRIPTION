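Package: condquant
Title: Quantification of Transcription-Factor Condensates in Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for quantifying nuclear transcription-factor
    condensates in yeast fluorescence microscopy: per-nucleus pixel-intensity
    dispersion statistics (coefficient of variation, Fano number, and
    reference-normalized Fano), per-cell two-channel pixel co-localization,
    chromatin-dot-centered image alignment and population averaging with line
    profiles, fluorescence-recovery-after-photobleaching (FRAP) normalization
    and single-exponential fitting, and in vitro droplet segmentation with
    partition coefficients. Ships a synthetic-microscopy generator (nuclear
    scenes with puncta and locus dots, FRAP series, droplet fields) with known
    ground truth, so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    EBImage,
    tiff,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
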