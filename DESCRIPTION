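Package: thrombonarx
Title: Predicting Individual Platelet Dynamics Under Chemotherapy with
    NARX Networks and Mechanistic Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to forecast daily platelet counts of individual patients
    under cytotoxic chemotherapy. Combines a semi-mechanistic
    transit-compartment model of thrombopoiesis (proliferating compartment,
    three maturation compartments, circulating platelets, feedback on
    proliferation) with small nonlinear autoregressive networks with
    exogenous therapy input (NARX), in feed-forward and gated-recurrent-unit
    variants. Individual networks can be pre-trained on trajectories
    simulated from the fitted mechanistic model (transfer learning), then
    recalibrated and fine-tuned on the patient's real counts. Includes
    clinically grounded evaluation (modified mean-squared error on log
    counts, NCI thrombocytopenia grading, nadir degree differences), a
    synthetic cohort generator emulating 6-cycle CHOP-like regimens, and
    experiment orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
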