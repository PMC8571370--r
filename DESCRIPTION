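Package: numtriage
Title: Triage of Mitochondrial Clone Libraries for NUMTs, Heteroplasmy and
    PCR Error
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Separates genuine mitochondrial haplotypes, Taq polymerase
    error variants, heteroplasmic copies, and nuclear mitochondrial
    pseudogenes (NUMTs) in clone libraries of PCR-amplified mtDNA
    fragments. Provides in-silico PCR and primer trimming, affine-gap
    pairwise and progressive multiple alignment, Kimura two-parameter
    distances under pairwise deletion with column-bootstrap standard
    errors, neighbor-joining trees with bootstrap support, invertebrate
    mitochondrial-code codon diagnostics, a rule-based clone triage, a
    Sanger electropherogram peak-multiplicity model for co-amplified
    haplotype mixtures, and a clone-library simulator with per-cycle
    polymerase error for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    phangorn,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
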