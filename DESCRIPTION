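Package: autobeat
Title: Contractility, Strain, Calcium and Action-Potential Analysis for
    Stem-Cell-Derived Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis channels for quantifying the autonomous beating
    behaviour of stem-cell-derived cardiomyocyte aggregates (embryoid
    bodies): segmentation-based fractional-area-change traces and beat
    frequency from bright-field video, multi-pass cross-correlation
    particle image velocimetry with contraction-positive strain-rate
    metrics (cumulative strain, strain per beat), calcium-transient
    feature extraction (time to peak, full width at half maximum,
    exponential decay time constant), action-potential feature extraction
    (maximum diastolic potential, upstroke velocity, APD30/50/90) with
    Tukey-fence classification of rapidly depolarizing cells, and
    delta-delta-Ct relative quantification for qPCR. Includes a synthetic
    data generator that produces contracting speckled videos, fluorescence
    transients, spontaneous action-potential trains and Ct tables with
    full ground truth for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    EBImage,
    minpack.lm,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
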