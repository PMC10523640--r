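Package: mbforage
Title: Mushroom-Body Plasticity Rules and Operant Matching in Dynamic Foraging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis tools for baited two-odor dynamic-foraging
    behavior. Provides a mushroom-body-inspired generative agent (sparse Kenyon
    cell odor representations, plastic KC-to-MBON synapses with a sigmoidal
    reject readout, and four candidate reward-dependent plasticity rules,
    covariance-based and not), matching-law analytics (instantaneous and
    block-averaged choice/reward fractions, undermatching, transition dynamics,
    win-stay/lose-switch tables, history-conditional choice probabilities),
    descriptive choice models (history logistic regressions with shuffle
    controls, leaky-integrator value model with timescale estimation), and a
    regression framework that infers which plasticity rule generated an
    accept/reject sequence by comparing deviance explained across rule variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
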