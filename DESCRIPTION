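Package: cetzkit
Title: Subfamily Residue Signatures and Gene-Neighbourhood Analysis for
    Archaeal CetZ Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising tubulin-superfamily protein
    subfamilies in archaea. Builds per-group consensus profiles from a
    grouped multiple sequence alignment and calls subfamily-discriminating
    ("unique") residues with a mean-consensus score and a residue-chemistry
    classification; extracts fixed-flank genomic windows (40 kb by default)
    around focal genes on linear or circular contigs, tallies arCOG
    orthologous-group occurrence and cross-species presence, calls conserved
    neighbourhood genes, classifies type IV pili regulon association, and
    emits strand-normalised synteny tables; tabulates co-occurrence of CetZ
    subfamilies with reported motility and rod-shape phenotypes across
    species; and generates seeded synthetic alignments, annotated genomes
    and species tables with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    ggplot2,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
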