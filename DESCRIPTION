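Package: L1Detect
Title: Seed-and-Pattern-Match Detection of LINE-1-Like Interspersed Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects full-length and degraded copies of LINE-1-like
    interspersed repeats in assembled genomes using a seed-and-pattern-match
    strategy. Conserved k-mer probes are derived from an aligned query set,
    mapped approximately onto a target genome on both strands (Levenshtein
    distance bounded by delta), and chained into pattern matches: ordered
    runs of at least m seeds whose inter-seed spacing agrees with the probes'
    average layout within a threshold t. Includes probe design by
    conserved-column scanning with three-step candidate refinement, GFF3
    annotation output, precision/recall/F1 evaluation with (m, t, delta)
    parameter sweeps, copy-number variation summaries, and a synthetic-genome
    simulator that plants intact, truncated and internally deleted element
    copies with ground-truth annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'L1Detect-package.R'
    'RcppExports.R'
    'annotation-io.R'
    'chaining.R'
    'cnv.R'
    'evaluation.R'
    'probe-design.R'
    'seed-mapping.R'
    'synthetic-genome.R'
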