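Package: circAS
Title: Alternative Splicing Detection and Comparison in Circular RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects circular RNA (circRNA) back-splice junctions from
    chimeric RNA-seq alignments, calls four classes of alternative-splicing
    events internal to each circRNA (exon skipping, intron retention, and
    alternative 5'/3' splice sites), and compares event catalogs between
    conditions (for example tumour versus adjacent normal tissue) to
    classify events as condition-specific or common. Junctions are filtered
    by the canonical GT-AG/CT-AC splice motifs and corrected against
    annotated exon boundaries. Includes a deterministic synthetic-data
    generator (mini-genome, GTF, SAM reads with planted events and decoys)
    for validation, downstream characterization (intron length, host
    biotype, gene-list overlap), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    S4Vectors,
    rtracklayer,
    optparse,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
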