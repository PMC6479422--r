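Package: svdepth
Title: Depth-Based Annotation and Filtering of Structural Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates structural variant (SV) calls in a VCF with two
    read-depth fold-change statistics computed from an indexed BAM or CRAM
    file: DHBFC, the median depth inside the event relative to the median
    depth of 250-bp reference windows of similar GC content, and DHFFC, the
    median depth inside the event relative to the median depth of the 1,000
    bases flanking each breakpoint. Per-base coverage is computed with a
    diff-array plus cumulative-sum algorithm whose cost is nearly
    independent of the number of variants annotated. Includes threshold
    filters and precision/recall/ROC machinery for evaluating filtered call
    sets, and a deterministic synthetic-fixture generator (reference FASTA,
    alignments, truth VCF with matched homozygous-reference null events) so
    the whole workflow can be exercised without external data.
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
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    methods,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
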