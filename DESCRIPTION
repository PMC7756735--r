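Package: smnscreen
Title: SMN1 Copy Number Estimation and Spinal Muscular Atrophy Carrier
    Screening from Short-Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates absolute SMN1 copy number and flags spinal muscular
    atrophy (SMA) carriers, including 2+0 "silent carriers", from batches of
    coordinate-sorted, indexed short-read alignment files mapped to GRCh37.
    Read support for the SMN1 and SMN2 alleles is counted at three
    paralog-discriminating positions, depth of coverage is normalized
    against 20 control genes across the batch, and simple centroid rules
    convert the per-sample scale factor and allele ratios into an
    SMN1:SMN2 genotype estimate.  A synthetic-alignment generator emulates
    arbitrary SMN1:SMN2 genotypes so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    parallel,
    stats,
    utils,
    tools,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
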