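Package: drldyn
Title: Mutational Dynamics of Genome-Wide Short Tandem Repeat Length Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling genome-wide distributions of short tandem
    repeat (STR) tract lengths (DRLs) from nucleotide sequence, for evolving a
    DRL forward in time under an aggregate per-generation mutation kernel
    (substitutions plus length-instability expansions, contractions and
    non-motif insertions, including repeat fission and fusion), for grid-based
    Approximate Bayesian Computation over parameterized instability-rate
    curves with a Kullback-Leibler rejection kernel, and for analytic and
    numerical characterization of the steady-state distribution. Includes a
    sequence-level forward simulator used as an independent oracle for the
    binned kernel, and synthetic-data generators (random genomes, perturbed
    DRL ensembles, labelled de novo mutation events) so the whole pipeline is
    exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
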