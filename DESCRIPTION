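Package: fcglung
Title: Chromosomal Versus Gonadal Sex Effects in Neonatal Hyperoxic Lung
    Injury Transcriptomics
Version: 0.1.0
Authors@R:
    person("fcglung", "developers", email = "fcglung@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for dissecting sex-chromosome-complement
    versus gonadal-hormone effects on the neonatal hyperoxia response in
    the Four Core Genotypes (FCG) mouse design.  Provides a negative
    binomial simulator for 2x2x2 factorial RNA-Seq studies with planted
    chromosomal-by-treatment interactions, X-escapee and Y-only genes;
    variance-moderated two-group differential expression with directional
    signatures; four-way directional Venn decomposition of genotype
    responses into gonadal and chromosomal regions; summed Z-score
    projection of murine signatures onto an external human-style cohort
    with sex-stratified clinical association; preranked gene-set
    enrichment with permutation NES and FDR; three-way ANOVA with
    Sidak-adjusted post hoc comparisons; and a one-command synthetic
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
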