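Package: psmb8typer
Title: Allele Typing and Lineage Classification of Holostean PSMB8 Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies immunoproteasome subunit PSMB8 coding sequences in
    transcriptome contigs, maps them to mature-protein coordinates via the
    conserved TTTL cleavage motif, calls the functional type at mature residue
    31 (A, F, S and K types), classifies sequences into the ancient A and F
    allelic lineages using eight diagnostic residues, profiles the S1
    substrate-binding pocket, summarises codon usage at the type-defining
    codon, and places sequences into a distance-based phylogeny with bootstrap
    support and PSMB5 outgroup rooting. Includes a synthetic transcriptome
    generator with truth tables so every stage of the pipeline can be
    validated without external data.
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
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
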