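Package: c1readout
Title: Choice Probability Analysis of the C1 Visual Evoked Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for testing whether the earliest
    visual evoked potential component (the C1, ~80-90 ms, generated by initial
    afferent V1 activity) carries choice probability in speeded contrast
    discrimination. Provides a synthetic-data generator (contrast grating
    stimuli, a two-stage accumulator observer, and a multichannel EEG forward
    model with injectable artifacts), FIR preprocessing with artifact screening,
    single-trial C1 measurement and a comprehensive choice-signal search,
    sliding response-time-window logistic models with a bootstrap
    significance-run onset estimator, centro-parietal positivity slope analysis,
    and time-resolved linear discriminant decoding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
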