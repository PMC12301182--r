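Package: hgtbench
Title: Benchmarking Horizontal Gene Transfer Inference via Co-Acquisition Neighbor Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates genome evolution with segmental horizontal gene transfer
    (HGT), infers gene gains with asymmetric Wagner parsimony on phyletic
    patterns and with an oligonucleotide-typicality (Wn) detector, and
    evaluates any set of inferred gains by the genomic-neighborhood signal of
    co-acquired genes: the fraction of same-branch gene-pair acquisitions that
    are chromosomal neighbors, compared against an analytic chromosome-size
    null model. Inference sets are compared by the maximum Overlap Coefficient
    across stringency levels and clustered with UPGMA.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
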