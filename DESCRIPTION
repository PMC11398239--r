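Package: chestmorph
Title: Chest Morphology Assessment from Depth-Camera Point-Cloud Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for tracking breath-resolved chest-wall morphology of a
    supine patient from colorized RGB-D point-cloud sequences. Implements the
    full processing chain: a synthetic breathing-torso phantom generator with
    ground truth, PLY sequence input/output, saturation-channel circular Hough
    tracking of fiducial markers, rigid alignment to the table plane and
    nipple line, extraction of breath-induced depth-variation signals on a
    7 x 7 grid of square regions of interest, Butterworth smoothing and
    extrema-based breath separation, continuous-wavelet-transform artifact
    rejection, Gaussian breath-pattern gating between sessions, transverse
    cross-section morphometry with interquartile-range outlier cascade and
    medoid representative selection, and paired inter-session statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
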