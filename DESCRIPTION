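Package: lcsclust
Title: Greedy Incremental DNA Read Clustering with Longest Common
    Subsequence Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Greedy incremental clustering of short DNA reads at a sequence
    identity threshold, in the CD-HIT tradition. Candidate pairs are pruned by
    a cascade of two filters before the alignment step: a modified short-word
    (k-mer) filter that indexes only every k-th k-mer of each cluster
    representative, and a longest-common-subsequence (LCS) filter that bounds
    the attainable identity of a pair from above using a bit-parallel LCS
    length kernel. Surviving pairs are verified by optimal affine-gap
    alignment, with identity defined as matches divided by the shorter
    sequence length. Includes FASTA/FASTQ input, CD-HIT compatible '.clstr'
    output, a synthetic read-set generator with ground-truth cluster labels,
    and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
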