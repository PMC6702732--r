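Package: virosift
Title: Virus Discovery from Small RNA Size-Profile Signatures
Version: 0.1.0
Authors@R:
    person("Virosift", "Developers", email = "virosift@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies virus-derived small RNA signatures on
    assembled contigs. Computes strand-specific read-size profiles per
    contig, normalizes them with a z-score transformation, clusters the
    profiles with UPGMA on correlation distance, labels clusters as
    siRNA-like or piRNA-like (strand-biased) signatures, and recruits
    unclassified contigs of putative viral origin by profile correlation
    against classified virus contigs, including a host-contig
    reconstruction control. Also provides contig quality gates (length
    filter, greedy redundancy collapse, ORF functional-status tallies),
    log2-RPKM abundance matrices, species-composition filtering, and a
    continuity-corrected two-proportion chi-squared test for normalized
    small RNA counts. A seeded synthetic-data generator emulating siRNA,
    piRNA and degradation read populations makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
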