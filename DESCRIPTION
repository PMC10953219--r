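Package: rhsurvey
Title: Genome-Wide Gene-Family Survey Tools: Phylogeny, Duplication,
    Ka/Ks, Promoter Elements and qPCR Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a genome-wide gene-family survey
    workflow of the kind used for the RNA-helicase (DEAD/DEAH-box) family in
    rapeseed (Brassica napus): redundancy reduction and consensus-domain
    scanning to delimit the family; protein characterization (length,
    average molecular weight, isoelectric point by bisection on the
    Henderson-Hasselbalch charge equation); neighbor-joining phylogeny with
    column-bootstrap supports; paralog-pair calling with tandem versus
    segmental classification, Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor
    correction, and divergence dating T = Ks/(2*lambda); promoter
    cis-element scanning over IUPAC patterns in 2000-bp upstream regions;
    and qPCR relative expression by the comparative Ct (2^-ddCt) method
    with Welch tests and heat-matrix clustering. Ships synthetic-genome,
    codon-pair and Ct-table generators with machine-readable ground truth
    so every stage has an exact recovery test, plus transcriptions of the
    survey's printed gene and paralog tables as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
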