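Package: apoclass
Title: Hierarchical Molecular Apomorphy-Based Classification and Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines amino-acid apomorphies on a fixed rooted phylogeny by
    unit-cost parsimony with DELTRAN character optimization, filters them by
    consistency index and ambiguity, screens candidates per clade (sister-group
    overlap, missing-data coverage, uniqueness and multistate-trend criteria),
    encodes clades as hierarchical diagnostic barcodes with sequential base-36
    IDs, and identifies query organisms by a root-to-leaf barcode match with
    explicit missing-data semantics (missing residue vs missing gene). Includes
    a synthetic-data generator with planted apomorphies, tunable homoplasy and
    two missing-data processes, and an embedded 51-transcriptome query-test
    fixture for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    seqinr,
    tibble,
    tidyr,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
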