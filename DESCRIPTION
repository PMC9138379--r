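Package: cloneMeth
Title: Clone-Based Bisulfite Methylation Analysis of Plant Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clone-based (Sanger) bisulfite methylation analysis of
    promoter regions: sliding-window CpG-island prediction (GC content and
    CpG observed/expected ratio), in-silico bisulfite conversion and
    degenerate-primer PCR against converted templates, bisulfite-aware
    global alignment of cloned reads, per-cytosine methylation calling in
    the CpG, CpHpG and CpHpH contexts, per-colony summaries, and overlap of
    methylation marks with IUPAC-degenerate cis-regulatory motifs. Includes
    a synthetic-data generator (GC-structured references with planted
    islands and motifs, tissue-specific methylomes, simulated clone reads
    with configurable conversion efficiency and sequencing error) so the
    whole pipeline can be exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
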