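Package: stridemod
Title: Discovery and Dissection of Drug-Responsive Transcriptional Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering time-dependent, drug-induced
    gene expression modules in brain expression profiling experiments and for
    dissecting their regulation. Covers quantile normalization and batch
    z-score standardization, per-probe two-way (drug x time) ANOVA with
    Bonferroni and Benjamini-Hochberg adjustment and true-positive/FDR
    curves, Tukey drug-versus-saline contrasts, hierarchical pattern
    extraction with centroid-correlation extension, gene-set
    over-representation analysis, conservation-masked PWM scanning of
    promoter alignments for transcription-factor binding-site enrichment, a
    percent-inhibition statistic for pharmacological dissection experiments,
    pattern-phenotype correlation, and co-expression/regulatory network
    assembly. Ships a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    ape,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    car,
    jsonlite
Config/testthat/edition: 3
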