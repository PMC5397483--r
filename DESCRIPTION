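Package: streamseg
Title: Two-Stage Neuromechanistic Model of Auditory Stream Segregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the build-up of auditory stream segregation for ABA_
    triplet sequences with a two-stage model: rapidly adapting A1-like
    tonotopic inputs feed a three-unit stochastic firing-rate competition
    network (mutual inhibition, NMDA-like recurrent excitation, slow
    spike-frequency adaptation, Ornstein-Uhlenbeck noise) integrated with an
    Euler-Maruyama scheme over frozen-noise ensembles. Includes generators
    for the psychoacoustic paradigms (stimulus pauses, distractor tones,
    deviant tones), percept readout and build-up analysis, difference
    scores, distractor-frequency sweeps, a calibration harness, audio
    synthesis of the stimuli, and a configuration/reproducibility layer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
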