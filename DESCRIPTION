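Package: svscout
Title: Structural Variant Calling from Long-Read Alignments with a
    CNN-Transformer Window Classifier and Mean-Shift Breakpoint Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects germline structural variants (deletions, insertions,
    duplications, inversions and translocations of 50 bp and larger) from
    coordinate-sorted long-read BAM files. Per-site alignment features are
    summarised into stranded count matrices, scanned by a small
    convolutional network with channel/spatial attention whose 200 bp
    submatrix embeddings are contextualised by a transformer encoder;
    positive submatrices are merged into candidate regions, read-level
    signatures are extracted from CIGAR strings and split-read SA tags,
    breakpoints are grouped by kernel-density mean-shift clustering with
    SV-type- and error-rate-dependent bandwidths, calls are filtered by a
    coverage-adaptive minimum-support rule and genotyped by a vote over
    Bayesian, expectation-maximisation and read-ratio genotypers, and
    results are written as VCF 4.2. A built-in simulator constructs
    reference sequences, implants variants and emits analytically aligned
    BAM records so that training, calling and evaluation run end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
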