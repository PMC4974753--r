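Package: ssrmine
Title: Genome-Wide Microsatellite Mining, Cross-Species Marker Transfer, Synteny
    and Diversity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects perfect and compound microsatellites (SSRs) of 2-8 bp motifs
    under per-class minimum-length rules, designs flanking PCR markers with a
    simplified nearest-neighbor primer picker, tests cross-species marker
    transferability by electronic PCR under an asymmetric 5'-mismatch rule,
    calls collinear and inverted syntenic blocks from markers shared between
    genomes, and computes codominant-marker diversity statistics (Na, Ne, Ho,
    He, Shannon's I, PIC), allele-sharing distances, UPGMA dendrograms and the
    Evanno delta-K statistic. Ships synthetic-data generators that plant SSR
    loci, chromosomal rearrangements, population-structured genotypes and
    log-probability tables with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
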