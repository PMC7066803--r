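Package: famcurate
Title: Gene-Family Curation by Phylogenetic Consensus, Synteny and
    Nomenclature Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating a vertebrate gene family across teleost and
    mammalian genomes, modelled on the connexin (gap junction protein) family.
    Provides structured-label and locus-table parsing, conserved-domain
    extraction, alignment site filtering, evolutionary distances,
    neighbor-joining, minimum-evolution and maximum-parsimony tree
    reconstruction with bootstrap support, consensus classification of
    orthologous groups across a grid of analyses, synteny-based inference of
    ohnolog versus tandem duplicates, rule-based nomenclature harmonization
    and renaming proposals, assembly quality screening for missing genes,
    duplicate artifacts and breakpoints, and a gene-family evolution
    simulator with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
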