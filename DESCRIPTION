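Package: lfpmark
Title: Sharp-Wave Ripple and Gamma Analysis of Hippocampal Field
    Potentials with CSF Biomarker Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for extracellular hippocampal field
    recordings and cerebrospinal-fluid biomarker cohorts. Detects
    sharp-wave ripples on the RMS envelope of the 150-250 Hz band-passed
    trace with Morlet-wavelet boundary and peak-frequency estimation and
    the standard duration and RMS rejection rules; quantifies
    carbachol-gamma oscillations via 1/f-normalized, z-scored Welch power
    spectra and tiered single-unit/hypersynchronous-burst detection on the
    300 Hz high-passed trace; and evaluates CSF analytes as diagnostic
    biomarkers (ROC, AUC, Youden-index cutoff, accuracy, ratio markers,
    hippocampal occupancy, Pearson correlation tables, two-group tests).
    Includes seeded generators for ground-truthed synthetic LFP recordings
    (1/f background, implanted ripples, gamma epochs, units and bursts)
    and two-group biomarker cohorts with targeted correlations, so the
    whole pipeline is testable without original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
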