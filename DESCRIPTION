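Package: tncscout
Title: Detection and Characterization of Translational Noncrystallographic Symmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects translational noncrystallographic symmetry (TNCS) in
    macromolecular crystals from merged X-ray diffraction intensities.
    Computes band-limited Patterson functions by FFT, picks and filters
    off-origin peaks with calibrated distance, peak-height and Z-score
    thresholds, analyses commensurate (pseudo-cell) modulation of the
    noise-reduced Patterson, and emits a ranked list of TNCS hypotheses
    that always includes the no-TNCS case.  Models the resulting intensity
    modulation with per-reflection expected-intensity (epsilon) factors,
    summarizes modulation strength by the variance of the epsilon factors
    about one, and refines the TNCS rotational perturbation and r.m.s.d.
    by maximum likelihood under the Wilson intensity distribution.  A
    coordinate-space closed-group analysis of atomic models provides the
    ground-truth classifier, and a synthetic point-atom crystal generator
    with direct-summation structure factors serves as an independent
    oracle for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    pROC,
    withr,
    yaml,
    ggplot2
Config/testthat/edition: 3
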