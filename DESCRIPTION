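Package: vascgro
Title: Vascular Tumour Growth Dynamics Under Antiangiogenic Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates vascular tumour growth with a dynamic carrying
    capacity and an avascular floor volume, coupled to a two-compartment
    intravenous-infusion pharmacokinetic model of an anti-VEGF antibody
    (bevacizumab) with multi-dose superposition.  Provides the analytic
    post-vascular dormancy (plateau) volume, plateau detection on simulated
    trajectories, treatment-effect endpoints (tumour growth inhibition and
    growth delay), one-at-a-time parameter perturbation analysis with
    biologically motivated parameter bounds, a two-stage bounded nonlinear
    least-squares calibration against xenograft tumour-volume series, and a
    synthetic-data generator emulating mouse xenograft experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
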