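Package: restex
Title: Extraction of Resting-State Analogues from Task fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting resting-state-like signal from block-design
    task fMRI and for quantifying how well the result resembles continuously
    acquired rest. Implements five extraction strategies (unmodified data,
    baseline-block concatenation with fixed or subject-adaptive cutting
    intervals, task regression, and regression followed by concatenation),
    per-subject hemodynamic-delay estimation by shifted-boxcar correlation,
    seed-based functional-connectivity mapping (nuisance regression with a
    global-signal toggle, zero-phase band-pass filtering, Fisher-z seed
    correlation), and map-similarity evaluation (intraclass correlation,
    thresholded Dice, R-squared) with repeated-measures group statistics.
    Ships a synthetic multi-subject BOLD generator with known network
    structure and hemodynamic delays so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
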