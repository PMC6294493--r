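Package: roquinscan
Title: Discovery of Roquin-Bound Decay Elements (CDEs and ADEs) in 3'UTRs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scans mRNA 3'UTR sequences for constitutive decay elements (CDEs,
    6-8 bp hairpin stems capped by a YRN tri-nucleotide loop) and alternative
    decay elements (ADEs, GUUYUA hexaloop hairpins) recognised by the Roquin
    proteins.  Computes the exact thermodynamic probability that each
    candidate hairpin forms within its UTR context under a nearest-neighbor
    energy model (partition function, base-pair probabilities, minimum free
    energy structure), classifies evolutionary conservation of each element
    across a five-mammal alignment using structure-aware tolerated-change
    rules (compensatory pairs, wobble pairs, stem-length changes,
    consensus-preserving loop changes), runs composition and enrichment
    statistics, and selects high-confidence targets.  Ships a synthetic-data
    generator producing FASTA/MAF fixtures with ground truth so every stage
    is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
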