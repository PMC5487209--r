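Package: tmddrebound
Title: Receptor Rebound in Target-Mediated Drug Disposition Models with
    Homeostatic Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing post-dose receptor rebound in
    target-mediated drug disposition (TMDD) models in which the receptor
    synthesis rate experiences homeostatic negative feedback, either
    directly (quasi-equilibrium) or through a dynamic feedback moderator.
    Provides constructors and validation for feedback functions,
    non-dimensionalisation of the model, closed-form eigenvalues and
    feedback-speed thresholds of the baseline linearisation,
    theorem-based rebound classifiers, stiff ODE simulation with
    trajectory-based rebound detection and feedback-speed scans, and the
    five-state efalizumab/psoriasis indirect-response model with its
    reduction to the generalised feedback framework.  Ships transcribed
    parameter sets for omalizumab and efalizumab, and a small command
    line interface.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
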