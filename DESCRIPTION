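Package: dupchar
Title: Characterization of Tandem Segmental Duplications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize recent tandem segmental duplications from
    assembled sequence: k-mer self-comparison and chaining to call duplication
    boundaries, anchored affine-gap alignment of the two copies, sliding-window
    identity profiling and longest-identical-tract detection, classification of
    alignment gaps into double-strand-break repair signatures (microhomology
    jumps and tandem-repeat slippage) to polarize the neosynthesized copy,
    decomposition of the inter-copy junction into transposable-element/repeat
    modules with terminal-inverted-repeat and target-site-duplication
    annotation, in silico restriction digests and PCR, delta-delta-Ct relative
    quantification of copy number from qPCR replicate tables with exact
    rank-sum testing, and a Poisson identity-survival model that dates the
    duplication from the length of the fully identical tract. Includes a
    seeded, ground-truthed synthetic fixture generator emulating the X-linked
    sex-ratio duplication of Drosophila simulans so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    BiocGenerics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
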