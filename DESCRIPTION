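Package: mycobnet
Title: Bacterial-Fungal Gut Microbiome Dysbiosis Analysis with
    Interkingdom Association Networks
Version: 0.1.0
Authors@R:
    person("mycobnet", "developers", email = "mycobnet@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for two-kingdom (bacterial 16S and
    fungal ITS) gut microbiome case-control studies: alpha diversity
    (Shannon, reciprocal Simpson, Chao1, ACE), beta diversity
    (Bray-Curtis, unweighted/weighted UniFrac) with principal coordinate
    analysis and PERMANOVA, LEfSe-style linear discriminant analysis
    effect-size screening of differentially abundant taxa,
    prevalence-filtered within-kingdom (Spearman) and interkingdom
    (distance correlation with permutation testing) association networks
    compared by relative connectedness and node degree, and a genus-panel
    logistic-regression classifier evaluated by ROC AUC with bootstrap
    confidence intervals.  Includes a synthetic two-kingdom count-table
    generator with planted differential taxa and group-specific latent
    correlation structure so every stage can be validated against a known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    igraph,
    phyloseq,
    optparse
Config/testthat/edition: 3
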