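Package: resonmap
Title: Impedance and Resonance Functional Maps in Compartmental Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how dendritic morphology shapes steady-state and
    frequency-dependent response properties of hippocampal pyramidal neuron
    models. Reads and writes SWC morphologies, generates stylized CA1-like
    trees, produces atrophy series by uniform pruning across radial strata,
    discretizes trees with the d-lambda rule, assigns sigmoidal gradients of
    passive properties and HCN (h) channel density, integrates the resulting
    branched cable equations implicitly, and extracts nine functional maps
    (input resistance, local and transfer impedance amplitude, resonance
    frequency, resonance strength, total inductive phase) from chirp-current
    responses. Also quantifies the spatial influence field of a localized HCN
    conductance cluster on input resistance and resonance frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    pracma,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
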