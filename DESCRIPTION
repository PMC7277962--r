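Package: erpmark
Title: ERP Biomarkers of Antidepressant Treatment Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for event-related-potential (ERP)
    biomarkers of antidepressant treatment outcome in major depressive
    disorder. Extracts frontal alpha asymmetry (low alpha band, 8-10 Hz),
    the loudness dependence of auditory evoked potentials (LDAEP, N1/P2
    peak-to-peak slope across tone intensities), and mismatch negativity
    (MMN) amplitude from multichannel EEG; classifies remission and
    treatment response from Hamilton depression (HAM-D) trajectories; and
    runs the cohort statistics (median-split grouping, Pearson chi-square,
    Greenhouse-Geisser-corrected repeated-measures ANCOVA, per-week ANCOVA,
    partial correlation with covariates). A synthetic-data module generates
    EEG recordings and clinical cohorts with known ground truth so every
    stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
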