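Package: vrattn
Title: Multimodal Neurophysiological Analysis of Classroom Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multimodal recordings (EEG, 3D eye gaze,
    skin conductance, behavior) collected while listeners attend continuous
    speech in a virtual classroom with occasional background sound-events.
    Implements temporal response function (TRF) encoding and decoding of the
    speech envelope with ridge regression and shuffled-pairing permutation
    tests, event-related potentials with spatio-temporal cluster permutation
    statistics and 2x2 mixed ANOVA, periodic/aperiodic spectral decomposition
    with personal alpha and beta peaks, tonic/phasic electrodermal
    decomposition by non-negative deconvolution, dispersion-based 3D fixation
    detection with region-of-interest dwell and gaze-shift metrics, and
    group-level multivariate statistics including Bayes factors and dominance
    analysis. A synthetic session generator with known ground truth makes
    every stage testable without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
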