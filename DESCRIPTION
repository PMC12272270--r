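Package: fixfmri
Title: Fixation-Based Event-Related fMRI Analysis of Visual Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for fixation-based event-related
    fMRI experiments on multiple-target visual search. Provides a synthetic
    experiment generator (search displays, 500 Hz gaze traces, behavioral
    responses, and 4D BOLD volumes with known ground-truth effects), a
    velocity/acceleration saccade parser with refixation collapsing and
    fixation ranks, exact fixation-rank matching of target and rare-distractor
    fixations to common-distractor fixations, a canonical-HRF general linear
    model with AR(1) prewhitening, cosine high-pass drift regressors and
    cluster-level FWE inference by sign-flip permutation, region-of-interest
    percent signal change, and a searchlight multivoxel pattern analysis with
    leave-one-run-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
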