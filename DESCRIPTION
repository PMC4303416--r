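Package: edrs
Title: Time-Varying Respiratory System Elastance from Ventilator Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Breath-by-breath estimation of the time-varying respiratory
    system elastance (Edrs) of spontaneously breathing, partially
    ventilated patients from airway pressure and flow, using a
    single-compartment model with a fixed airway resistance. Includes
    breath segmentation from flow waveforms, normalisation of Edrs
    trajectories onto a common inspiratory-time grid, percentile
    trajectory summaries and the AUC Edrs severity metric, per-patient
    statistical comparison of Pressure Support and Neurally Adjusted
    Ventilatory Assist sessions, and a forward simulator of spontaneous
    breathing under both modes that supplies analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
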