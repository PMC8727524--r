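Package: drgephys
Title: Simulation and Analysis of Sensory Neuron Excitability in Current Clamp
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A conductance-based single-compartment model of a small/medium
    dorsal root ganglion (DRG) sensory neuron with an explicit
    hyperpolarization-activated (HCN, Ih) current, together with the
    current-clamp protocols, action-potential and passive-property feature
    extraction, qPCR relative-expression (2^-ddCt) quantification, and cohort
    statistics needed to study HCN-dependent hyperexcitability. Genotype
    presets (wild type versus Fmr1 knockout, modelled as a reduced HCN
    conductance), lognormal cell-to-cell variability, and in-silico channel
    block (ZD7288, XE991) support virtual cohort experiments that link reduced
    HCN conductance to increased input resistance, reduced voltage sag, lower
    rheobase and increased firing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
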