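Package: asbdose
Title: Adaptive Seamless Bayesian Dose-Response Design for Crossover
    Neuromodulation Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing adaptive seamless Bayesian
    (ASB) dose-response studies built on a longitudinal tinnitus-loudness
    surrogate endpoint. Implements the piecewise hierarchical nonlinear
    model (linear pre-stimulation drift, transient bridge, four-parameter
    logistic online response, exponential post-stimulation decay) for
    10-point Likert loudness trajectories observed 21 times per session in
    a three-treatment Williams crossover; MCMC fitting with the
    Gelman-Rubin, Geweke and Heidelberger-Welch convergence battery;
    derived dose quantities (gain, carry-over, minimum/maximum effective
    dose and the mA-minute dose mapping); coefficient-of-variation,
    repeated-measures and dose-contrast sample-size calculators in point
    and posterior-distribution form with sequential sampling plans; the
    uncertainty-reduction statistic; the processed-delta adaptive decision
    engine; a synthetic trajectory simulator; and a session-protocol
    generator (loudness probes, picture blocks, emotional Stroop task).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    coda,
    grDevices,
    graphics,
    jsonlite,
    rjags,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
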