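Package: gazesync
Title: Simultaneous Multi-Participant Eyetracking for Economic Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A star-network coordinator for running interactive economic
    games with one eyetracker per participant, with simulated trackers
    standing in for hardware. Provides a newline-delimited message protocol
    and CSV session logs, a 60 Hz gaze-stream simulator with configurable
    accuracy noise, unsupervised policy-driven calibration, gaze-contingent
    synchronization barriers, selective recording windows, an iterated
    two-player public goods game with screen layouts and areas of interest,
    dispersion-based (I-DT) fixation detection, dwell and relative-attention
    measures, and models of round-by-round contributions: conditional
    cooperation strategies and a matching model whose attention weight is
    estimated per individual and linked to gaze-derived relative attention.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
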