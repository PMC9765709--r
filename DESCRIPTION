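Package: rrnppa
Title: Discovery and Classification of RRNPPA Peptide Quorum-Sensing Systems
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to discover cytoplasmic peptide quorum-sensing
    receptor-pheromone systems of the RRNPPA family (Rap, Rgg, NprR, PlcR,
    PrgX, AimR, ComR) in Firmicutes-like genomes and to classify their
    pheromone architecture. Includes per-subfamily position-specific
    scoring models with extreme-value score calibration, small-ORF and
    signal-peptide detection in receptor gene flanks, mature-peptide
    pseudorepeat analysis, export-pathway (SEC/SPI vs SEC/SPII) and
    genomic-context summaries (chromosome, prophage, plasmid,
    phage-plasmid), eavesdropper/chatterer role classification, and
    RMSD-based structural clustering with UPGMA/NJ dendrograms. A
    synthetic-genome generator with planted ground truth exercises the
    whole pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
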