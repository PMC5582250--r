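Package: mirEST
Title: Homology-Based Discovery of Conserved Plant miRNAs from EST Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully scripted pipeline for discovering conserved
    plant microRNAs in expressed sequence tag (EST) collections. Known mature
    miRNAs are used as homology probes (ungapped scan within a mismatch
    budget), redundant and protein-coding ESTs are removed, candidate
    precursor windows are folded with an embedded nearest-neighbour
    minimum-free-energy dynamic program, and candidates are screened on
    hairpin geometry, MFE, AMFE, MFEI and GC content. Companion modules score
    miRNA-target complementarity with an expectation-penalty scheme, detect
    simple tandem repeats, and build neighbour-joining trees from pairwise
    identity distances. A synthetic-data generator plants precursor hairpins,
    coding decoys and repeat decoys in background ESTs so the whole pipeline
    is benchmarkable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
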