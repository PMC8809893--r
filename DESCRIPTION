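Package: lcpupil
Title: Coupling Analysis of Locus Coeruleus Spiking and Pupil Diameter
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the moment-by-moment relationship between
    locus coeruleus (LC) spiking and pupil diameter in paired
    electrophysiology/pupillometry recordings.  Groups spikes into clusters by
    the unit's median interspike interval, measures cluster-triggered peak
    pupil responses, detects pupil dilation events from zero-crossings of the
    smoothed pupil derivative, and evaluates how well an ideal observer can
    decode spiking from pupil (and vice versa) via ROC/AUC analysis with a
    d-prime performance threshold.  Includes the resampling machinery used for
    optogenetic session comparisons (bootstrap confidence intervals,
    with-replacement permutation tests, within- versus across-session
    variability), signal-detection behavioral metrics for Go/NoGo sessions, an
    optical-fiber excitable-volume estimate, and a synthetic paired-recording
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    zoo,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
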