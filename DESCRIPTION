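Package: epistim
Title: Ion-Dynamics Neural Mass Modelling of Seizures and Low-Frequency
    Electrical Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a modified Epileptor-2 neural mass model of
    recurrent seizure-like events in high-potassium hippocampal tissue,
    tracking membrane potential, synaptic depression, extracellular
    potassium and intracellular sodium together with Na-K pump activity.
    Provides impulsive low-frequency electrical stimulation (LFES)
    protocols, bath-potassium step and ramp schedules, seizure
    onset/offset detection with inter-seizure-interval extraction,
    stimulation parameter sweeps with relative seizure-delay statistics,
    fast-subsystem bifurcation analysis (folds and Hopf point), and a
    synthetic local-field-potential generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
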