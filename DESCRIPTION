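Package: washomics
Title: Repeat-Dose and Washout Multi-Omics Differential Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential analysis and integration of repeat-dose/recovery
    (washout) multi-omics experiments in cultured cells. Implements
    empirical-Bayes moderated t-tests for mRNA and miRNA expression arrays,
    probe sliding-window ANOVA region calling for promoter tiling arrays
    (histone acetylation ChIP-chip and DNA methylation MeDIP-chip), QC-RLSC
    LOESS drift correction for injection-ordered GC-MS metabolomics, and an
    integration layer: per-condition impact counts, epigenome-transcriptome
    Spearman coupling, post-washout persistence of epigenetic marks,
    mark/expression concordance classification, cross-treatment miRNA
    overlap, and positive-control-gated stress-pathway ranking. A synthetic
    data generator with planted ground truth emulates the full study design
    (treatments x timepoints x replicates, recovery phase, injection-order
    drift) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
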