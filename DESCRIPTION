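Package: mirgallus
Title: Two-Library Small RNA-Seq miRNA Analysis for Divergent Chicken Breeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable, fully testable re-implementation of a two-library
    small RNA sequencing analysis of chicken skeletal muscle: adapter trimming and
    read collapsing, exact genome mapping, priority-cascade annotation against
    miRNA/ncRNA/mRNA/repeat catalogs, isomiR and miRNA/miRNA* arm profiling,
    differential expression between two sequencing libraries by a Poisson
    likelihood-ratio test, rule-based cross-species conservation classification
    with a base-pair-maximization secondary-structure fold, novel-candidate
    discovery with a permuted-dataset signal-to-noise control, and construction of
    a miRNA-target interaction network from seed matching, opposite-expression
    filtering and correlation-filtered protein-protein interactions. A synthetic
    data generator emulates two-breed read libraries with planted ground truth so
    the whole pipeline runs and is validated without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
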