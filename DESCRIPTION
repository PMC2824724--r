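Package: mirstage
Title: Stage-Resolved Small RNA Processing and miRNA Discovery for Silkworm Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for barcoded small RNA sequencing libraries sampled
    across the four developmental stages of the silkworm (feeding larva,
    spinning larva, pupa, moth): demultiplexing, adapter trimming, collapsing
    to unique tags, a hierarchical annotation cascade against non-coding RNA,
    repeat, messenger RNA and known-miRNA references, genome mapping, hairpin
    fold-back prediction by base-pair maximization, miRNA-star inference under
    the 2-nt 3' overhang duplex geometry, seed-based family clustering with
    family rescue, antisense-locus detection, siRNA-locus disqualification,
    and stage-wise expression statistics (TPM, abundance shares, fold changes,
    miR:miR* ratios, temporal classes). Includes a synthetic-data generator
    with a ground-truth manifest for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
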