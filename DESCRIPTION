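Package: sjquery
Title: Query Engine for Splice-Junction Compilations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A search engine for summarized RNA-seq splice-junction
    compilations. Combines a genomic interval index, ordered numeric
    indices over junction coverage summaries, and a term-document
    inverted index over sample metadata under one query planner, so that
    region (R), summary-filter (F) and metadata (M) constraints can be
    freely combined. On top of basic queries it implements four
    high-level splicing statistics: Shared Sample Count, Junction
    Inclusion Ratio, Percent Spliced In, and a Kruskal-Wallis based
    Tissue Specificity test. Includes a seeded synthetic-compilation
    generator with planted cassette-exon, tissue-specific and
    sample-outlier events for offline validation, and a command-line
    interface with stable TSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
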