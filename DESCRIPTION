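Package: rtpgame
Title: Simulation and Assessment Pipeline for Game-Based Hand Rehabilitation
Version: 0.1.0
Authors@R: person("RTP", "Maintainers", email = "rtpgame@example.org", role = c("aut", "cre"))
Description: Simulates a one-degree-of-freedom robotic manipulandum (handle
    angle mapped to a screen coordinate, with an optional unidirectional
    constant force field), runs a repetitive task practice "catch the falling
    target" game with frame-level logging, generates able-bodied and
    stroke-like virtual player responses, and computes the kinematic
    assessment metrics used in game-based upper-extremity rehabilitation:
    success rate, movement onset time, movement duration, amplitude,
    overshoots and trial-to-trial variability. Also provides Wolf Motor
    Function Test scoring, pre/post change scores, MCID flagging and the
    group summary tables used to report clinical feasibility outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
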