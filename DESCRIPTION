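Package: episcreen
Title: Two-Stage SNP-SNP Epistasis Screening and Cis-Epistasis Dissection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Knowledge-based screening for SNP-SNP statistical epistasis in
    multi-study case-control data: a fast linear interaction screen over four
    genetic encodings per SNP, inverse-variance fixed-effects meta-analysis,
    logistic refinement with multidimensional-scaling ancestry covariates, and
    Bonferroni thresholding on LD-independent SNP counts. Candidate pairs are
    prioritized by replication, linkage-disequilibrium and proxy criteria, and
    conditional likelihood-ratio tests discriminate genuine cis-epistasis from
    haplotype tagging of a rare variant. Flagged loci can be dissected with
    genotypic odds ratios, forward model selection, type-III term tests,
    inverse-normal trait association, EM haplotype-frequency estimation with
    haplotype GLMs, and AIC comparison of SNP, interaction and haplotype
    models. A synthetic-cohort generator with block-wise linkage
    disequilibrium, planted interactions and a rare tagged variant makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    car,
    withr
Config/testthat/edition: 3
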