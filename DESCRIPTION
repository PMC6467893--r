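Package: TMEprofiler
Title: Tumor Immune Microenvironment Profiling for NSCLC Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated analysis toolkit for multi-omic immune profiling
    of non-small cell lung cancer cohorts. Computes single-sample gene set
    enrichment (ssGSEA) immune signature scores and per-patient preranked
    enrichment calls from FPKM expression matrices, classifies samples into
    immune HIGH/MIX/LOW groups by hierarchical clustering with
    histology-specific refinement, merges multi-caller somatic variant calls
    and applies a four-step somatic filter cascade with mutational burden and
    substitution spectra, scores and ranks gene fusion candidates, summarizes
    segmented copy number into gene-level five-state calls, tests
    genotype-immune group associations, and performs Kaplan-Meier/log-rank
    and Cox survival analyses including a Firth-type penalized fit. A
    synthetic cohort generator with planted immune, genomic and survival
    structure makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    mclust,
    jsonlite
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneSetEnrichment, CopyNumberVariation,
    SomaticMutation, Survival, ImmunoOncology
RoxygenNote: 7.3.3
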