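Package: covhmm
Title: Annotation-Free Site-Level Expression Change Detection from
    RNA-Seq Coverage
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects site-specific gene expression changes from per-site
    RNA-seq read depth without relying on gene annotations. Coverage
    tracks are quantile normalized per chromosome, compared against a
    panel of reference replicates, and segmented with a three-state
    (decreased / stable / increased) hidden Markov model decoded by the
    forward-backward algorithm, with optional Baum-Welch re-estimation
    of transition probabilities. Downstream tools turn per-site state
    calls into expression blocks, gene-level and chimeric-gene
    upregulation calls, and de novo transcription calls; classify the
    structural consequences of tandem duplications (whole-gene,
    chimeric, gene fragment, recruited non-coding, intergenic) from
    divergently oriented read pairs; and provide dosage-sharing and
    enrichment statistics. A synthetic-data generator with known ground
    truth supports end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    limma,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
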