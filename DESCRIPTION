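Package: cvrquant
Title: Quantitative Cerebrovascular Reactivity from Dual-Echo ASL/BOLD and
    Phase-Contrast MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for quantitative cerebrovascular
    reactivity (CVR) mapping under a hypercapnic CO2 challenge. Processes
    dual-echo pseudo-continuous arterial spin labeling (pCASL) acquisitions
    into perfusion-weighted (surround subtraction) and BOLD (surround
    addition) time courses, extracts breath-wise end-tidal CO2 from
    capnograph recordings and aligns it to the brain signal by
    cross-correlation, computes ASL- and BOLD-based CVR maps and ROI
    summaries in percent signal change per mmHg, quantifies superior
    sagittal sinus blood flux from phase-contrast velocity maps to obtain
    PC-based CVR and basal cerebral blood flow, and reproduces cohort-level
    group contrasts adjusted for sex and site. Includes a fully seeded
    synthetic-subject generator (images, physiology, ground truth) so every
    stage is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
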