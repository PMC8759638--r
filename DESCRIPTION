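Package: minidomain
Title: Fragment-Size-Resolved CUT&RUN Analysis of Chromatin Domains and
    Their Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for paired-end CUT&RUN chromatin profiling that
    exploits fragment size to map, from a single experiment, both broad
    histone-modification domains (nucleosome-sized fragments, 150-250bp) and
    the sub-nucleosomal footprints (<120bp) of transcription-factor-bound DNA
    regulatory elements within or at the borders of those domains. Provides
    fragment I/O and binned coverage, a transparent Poisson local-background
    caller for short-fragment peaks with replicate reproducibility filtering,
    threshold-based segmentation of broad domains with size-normalized
    enrichment, border/internal peak classification, midpoint-versus-length
    (V-plot) matrices, meta-domain profiles, region quantification with
    condition contrasts, CUT&RUN-qPCR fold-enrichment arithmetic, IUPAC
    consensus motif scanning on both strands, and a synthetic fragment-library
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
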