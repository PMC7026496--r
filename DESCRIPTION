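Package: crossomics
Title: Cross-Species Precision-Medicine Pipeline for Drug Screens,
    Tumor Heterogeneity, Ubiquitinomics and PDX Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a comparative-oncology
    precision-medicine workflow built around a multi-tumor canine
    leiomyosarcoma case: DMSO-normalized high-throughput drug-screen
    analysis with percent-killing profiles, multi-threshold hit calling,
    target and pathway vulnerability ranking, compound clustering and
    four-parameter logistic IC50 estimation; somatic-variant heterogeneity
    from per-sample VCFs (SNV filtering, pairwise Jaccard similarity,
    UpSet-style intersection patterns, deleterious gene sets and a PDX
    contamination filter); binary presence/absence phylogenetics
    (neighbor joining, Fitch parsimony with exhaustive and NNI search,
    bootstrap support, majority-rule consensus); ubiquitin-remnant
    differential abundance with Benjamini-Hochberg control and
    hypergeometric pathway enrichment; mutation-by-ubiquitination
    candidate integration; and PDX caliper growth-curve analysis with
    censoring and two-way ANOVA. Seeded synthetic-data generators with
    planted ground truth make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
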