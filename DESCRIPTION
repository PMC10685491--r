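Package: pdnaflux
Title: Growth-Decoupled Plasmid DNA Bioprocess Design with Constraint-Based Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design of growth-decoupled plasmid DNA (pDNA) production processes in
    Escherichia coli fed-batch cultures using constraint-based metabolic modeling.
    Provides flux balance analysis (FBA), parsimonious FBA, and lexicographic FBA on
    stoichiometric models read from and written to SBML Level 3 with the FBC
    extension; construction of a parametric plasmid synthesis pathway from length,
    GC content, and ATP polymerization cost; identification of medium components
    whose withdrawal decouples pDNA synthesis from growth, with production
    envelopes; a lexicographic dynamic-FBA simulator of three-stage fed-batch
    processes switched by sulfate depletion; grid optimization of switching time
    and initial sulfate dose for average volumetric productivity, including
    breakthrough production lengths; screening of secreted products for
    sulfate-limitation benefit; and evaluation metrics (specific yield, volumetric
    productivity, finite-difference synthesis rates, plasmid copy number, arm
    comparisons) for measured or simulated bioprocess time series. Includes a
    small, closed-form-solvable sulfate-dependent test network and a generator of
    noisy synthetic measurement series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    deSolve,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
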