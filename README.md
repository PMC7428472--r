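# mycobnet

Bacterial-fungal gut microbiome dysbiosis analysis with interkingdom
association networks.

Case-control amplicon studies increasingly profile both the bacterial
microbiota (16S rRNA) and the fungal mycobiota (ITS) of the same stool
samples. `mycobnet` is an R toolkit for the statistical core of such
two-kingdom analyses — written for microbiome researchers who start from
genus/OTU count tables (QIIME-style TSV or BIOM) plus sample metadata and
want a reproducible, seeded pipeline from filtering to classification:

* **Alpha diversity** — Shannon (−Σ pᵢ ln pᵢ), reciprocal Simpson
  (1/Σ pᵢ²), bias-corrected Chao1 (S + F₁(F₁−1)/(2(F₂+1))) and ACE richness
  estimators, with two-group Wilcoxon tests.
* **Beta diversity** — Bray-Curtis (Σ|x−y|/Σ(x+y)), unweighted and
  normalized weighted UniFrac on a phylogeny, PCoA by classical scaling,
  and PERMANOVA group separation with permutation p-values.
* **Differential abundance** — a LEfSe-style screen: per-sample
  normalization to 10⁶, exact rank-sum filtering (p < .05), bootstrap LDA
  effect sizes, and the conventional report rule |LDA score| > 2.
* **Association networks** — within-kingdom Spearman networks on taxa
  present in > 50% of samples and interkingdom distance-correlation
  (dCor) networks with permutation tests on taxa present in > 20% of
  samples; groups compared by *relative connectedness* (significant
  edges / nodes) and Mann-Whitney tests on node degree.
* **Genus-panel classifier** — multivariable logistic regression on a
  named genus panel (presets: 4 bacterial, 4 fungal, and the combined 8),
  rank-formulation ROC AUC with stratified-bootstrap CIs and optional
  cross-validation.
* **Synthetic data with ground truth** — a log-normal→multinomial
  (Gaussian copula) generator that plants differential genera and
  group-specific cross-kingdom correlation structure, so every stage can
  be validated against a known answer.

## Worked example

Simulate the default case-control world (24 cases "CDE" vs 16 controls
"HC"; 100 bacterial + 60 fungal genera; 8 + 8 planted differential genera;
denser latent correlation in controls) and run the main stages:

```r
library(mycobnet)
sim <- simulate_tables(default_paper_like_scenario(seed = 7))
sim$bact
#> <abundance_table> bacteria: 40 samples x 100 taxa
#>   total counts: 966755 | taxonomy attached
```

Differential abundance on the major genera (mean relative abundance ≥ 1%):

```r
rb <- lefse(filter_major_genera(sim$bact), sim$meta$group, seed = 7)
rb[, c("taxon", "enriched", "p_value", "lda_score")]
#>                         taxon enriched  p_value lda_score
#> 7                 Lachnospira       HC 5.07e-08      4.53
#> 5                   Dialister       HC 1.11e-07      4.44
#> 3                     UBA1819      CDE 2.90e-07     -4.40
#> 6            Fusicatenibacter       HC 3.15e-05      4.39
#> 1                 Akkermansia      CDE 5.67e-07     -4.31
#> 2 Clostridium_sensu_stricto_1      CDE 5.00e-06     -4.11
#> 4                 Veillonella      CDE 8.69e-07     -4.04
#> 8                  Sutterella       HC 4.60e-03      3.99
```

All 16 reported features are planted ones: positive scores mark
control-enriched genera, negative scores case-enriched, and every report
satisfies p < .05 and |LDA| > 2. Per-group bacterial networks and the
connectedness comparison:

```r
g <- split(seq_len(40), sim$meta$group)
sub <- function(tb, i) abundance_table(tb$counts[i, , drop = FALSE],
                                       tb$kingdom, tb$taxonomy)
compare_networks(build_spearman_network(sub(sim$bact, g$HC),  "HC"),
                 build_spearman_network(sub(sim$bact, g$CDE), "CDE"))
#>   group nodes edges connectedness mean_degree sem_degree degree_p
#> 1    HC   100   355          3.55        7.10      0.327    0.315
#> 2   CDE   100   344          3.44        6.88      0.376    0.315
```

The control network is denser (higher edges/nodes ratio), reflecting the
planted contrast. Finally, the three genus-panel classifiers:

```r
fits <- lapply(c("bacterial4", "fungal4", "combined8"), function(p)
  fit_panel(sim$bact, sim$fungi, sim$meta, genus_panel(p),
            case_group = "CDE", n_boot = 2000, cv_folds = 5, seed = 7))
compare_panels(fits)
#>        panel   auc ci_low ci_high cv_auc
#> 1 bacterial4 0.990  0.961       1  0.982
#> 2    fungal4 0.951  0.870       1  0.909
#> 3  combined8 0.997  0.984       1  0.984
```

The combined eight-genus panel matches or beats both single-kingdom
panels — the qualitative pattern such studies report. `auc` is the
apparent (resubstitution) AUC; prefer `cv_auc` (stratified 5-fold) at this
sample size, for the reasons quantified in the methods vignette.

The full pipeline — filtering, diversity, differential abundance, both
network types, classifiers, and a deterministic JSON manifest — runs from
one config:

```r
cfg <- pipeline_config(scenario = default_paper_like_scenario(seed = 7),
                       seed = 7)
res <- run_pipeline(cfg, "results/run1")
```

or from the shell via `inst/scripts/pipeline.R`
(`Rscript inst/scripts/pipeline.R run --config cfg.json --out results/`).

## Documentation

See the methods vignette (`vignettes/mycobnet-methods.Rmd`) for the
generative model, every tunable threshold with its default and rationale,
what a green test does and does not establish, and known limitations —
including a measured analysis of bootstrap AUC confidence-interval
undercoverage at n = 40.
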