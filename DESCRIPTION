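Package: sirvpop
Title: Comparative Genomics and CRISPR Biogeography of Rudivirus Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for populations of Sulfolobus islandicus
    rod-shaped viruses (SIRVs) and their hosts: homologous gene clustering of
    ORF sets by Smith-Waterman bit-score-ratio screening and Markov
    clustering, core/variable pangenome partition with six-frame rescue of
    missed ORFs, Nei-Gojobori Pn/Ps and Jukes-Cantor distances with
    neighbor-joining trees, CRISPR repeat-spacer array detection, spacer to
    protospacer matching with seed and PAM criteria, immunity prediction
    against observed infection outcomes, and biogeographic summary
    statistics. Includes a seeded synthetic population generator with a
    ground-truth ledger so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    igraph,
    jsonlite,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
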