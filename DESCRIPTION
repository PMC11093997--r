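Package: marmonav
Title: Head-Gaze Kinematics and Hippocampal Coding Analyses for Freely Moving Primates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for freely moving primate hippocampus sessions:
    3D head-gaze kinematics from rigid-body quaternions, rapid head-movement
    detection with Naka-Rushton main-sequence fits, burst-index based
    pyramidal/interneuron classification, place and view spatial information
    with circular-shift permutation nulls, speed scores, Poisson GAM
    mixed-selectivity encoding with shuffle-gated forward model selection,
    pseudo-population place decoding with greedy ensemble construction, and
    head-movement-aligned LFP theta phase-reset statistics. Includes a
    synthetic-session generator with ground-truth manifests for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
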