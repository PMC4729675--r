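Package: rnafragdock
Title: Fragment-Based Docking of Single-Stranded RNA onto Proteins
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained, fragment-based docking of single-stranded RNA
    (ssRNA) onto protein receptors. Builds trinucleotide conformer libraries
    from protein-bound RNA structures, docks fragment ensembles rigidly with
    an 8-6 pair potential plus electrostatics on a precomputed receptor grid,
    filters poses by their propensity to form contiguous RNA chains via
    overlap-graph path counting, clusters poses at multiple radii, assembles
    and ranks candidate chains, and evaluates results against reference
    structures. Ships a deterministic synthetic benchmark generator for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
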