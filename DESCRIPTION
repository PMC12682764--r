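Package: lociscape
Title: Genome-Wide lncRNA Enrichment Window Ranking and Locus Architecture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks 100-kb genome windows by long non-coding RNA (lncRNA)
    transcript enrichment using three criteria (transcript hits, total
    transcript length, and length-by-expression weighted coverage), merging
    contiguous expressing bins into windows bounded by runs of more than two
    empty bins. Companion analyses classify lncRNAs by exon structure and
    orientation relative to gene segments (overlap and 500-bp proximity),
    extract virtual-4C viewpoint profiles from balanced Hi-C contact matrices
    with top-percentile interaction calling across replicates, compute
    stratum-adjusted correlation coefficients for replicate concordance, and
    normalize ATAC-seq peak scores to score-per-million with reproducibility
    filtering. A synthetic-data generator plants the statistical structure
    each stage assumes, so the whole pipeline runs and validates at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
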