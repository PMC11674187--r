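Package: cardioblock
Title: State-Dependent Cardiac Ion-Channel Block Analysis and Proarrhythmia
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in vitro cardiac safety pharmacology of sodium-channel
    blocking drugs. Builds the standard voltage-clamp protocol library and
    generates synthetic whole-cell patch-clamp sweeps from a ground-truth
    Markov model of Nav1.5 gating with conformation-specific drug block
    (modulated receptor hypothesis). Extracts peak currents, monoexponential
    inactivation time constants, Boltzmann activation/inactivation curves and
    action-potential metrics (APD90, resting potential) from sweeps. Estimates
    potency (single-point IC50 with control correction, Hill fits) and the
    four state-specific blocking/unblocking rate constants from use-dependent
    block recordings. Couples the resulting drug model to an O'Hara-Rudy 2011
    human ventricular cardiomyocyte model extended with a dynamic blocked-state
    variable, computing APD90 and the CiPA net-charge torsade-risk predictor
    Q_net, and to a one-dimensional 50-cell strand simulator quantifying
    conduction slowing and block under reduced gap-junction coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
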