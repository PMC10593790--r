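Package: photomotor
Title: Fiber Photometry, Pose Kinematics and Peri-Stimulus Spike Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dual-channel fiber photometry recorded
    during rodent behavior, together with pose-tracking kinematics and
    optogenetic electrophysiology. Computes isosbestic-corrected dFF and
    robust (MAD) z-scores, segments locomotor bouts and rotarod jumps from
    body-part tracking, aligns calcium transients to behavioral events,
    tests speed-signal coupling against phase-randomized surrogates, builds
    peri-stimulus time histograms and classifies units as inhibited or
    excited, and replays closed-loop optogenetic trigger rules offline. A
    seeded synthetic-data module generates photometry, tracking and spike
    trains with known ground truth so the whole pipeline is testable
    without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
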