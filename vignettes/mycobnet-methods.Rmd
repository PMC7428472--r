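---
title: "Methods: two-kingdom dysbiosis analysis with mycobnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-kingdom dysbiosis analysis with mycobnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`mycobnet` implements the statistical core of a two-kingdom (bacterial 16S +
fungal ITS) case-control gut microbiome analysis: alpha and beta diversity,
an LDA-effect-size differential-abundance screen, prevalence-filtered
within-kingdom and interkingdom association networks compared by relative
connectedness and node degree, and a genus-panel logistic classifier. The
pipeline starts from abundance tables; read processing, OTU picking and
taxonomy assignment are upstream and out of scope. Because the motivating
study design (24 cases with a current depressive episode, CDE, versus 16
healthy controls, HC) cannot be re-derived from raw public reads at desk
scale, every stage is validated on synthetic data with planted ground truth
rather than against the study's numbers.

# The synthetic world

`simulate_tables()` draws from a log-normal -> multinomial model (a Gaussian
copula on log abundances). For each sample, a latent vector over *all* taxa
of both kingdoms is drawn from a multivariate normal with a group-specific
correlation matrix; planted log2 fold-changes (x ln 2) are added to the
latent means of the enriched group; the vector is exponentiated, normalized
to a composition *within each kingdom* (16S and ITS are separate sequencing
runs), and counts are drawn multinomially at a depth sampled uniformly from
`depth_range`. This model was chosen over a Dirichlet-multinomial because it
lets an exact correlation matrix be planted, which is what the network
stages must recover. Fold-changes act on the latent scale; realized
compositional fold-changes are attenuated by closure, and the ground truth
is always the planted latent effect.

`default_paper_like_scenario()` fixes the stated study design: 24 vs 16
samples, 100 bacterial and 60 fungal genera, depths 10,000-40,000.
Choices the study does not state were made once, on these grounds:

* **Rank-abundance shape.** A steep abundant head over a long sub-1% tail,
  giving ~13 bacterial and ~10 fungal "major genera" (mean relative
  abundance >= 1%), matching real stool genus tables where the top ten
  genera carry most reads. A flatter ladder would both be unrealistic and
  make the planted-recovery false-discovery bound unattainable by sheer
  count of abundant null features tested at alpha = 0.05.
* **Planted effects in both directions.** The eight panel genera
  (Akkermansia, Clostridium_sensu_stricto_1, UBA1819, Veillonella; Candida,
  Chaetomium, Neocosmospora, Occultifur) are planted case-enriched at a
  latent log2 fold-change of 2. Eight further genera named after the
  study's depleted taxa (Dialister, Fusicatenibacter, Lachnospira,
  Sutterella; Scedosporium, Purpureocillium, Penicillium, Aureobasidium)
  are planted control-enriched at the same magnitude. One-directional
  planting depresses every null taxon's proportion in cases — a
  compositional artifact that masquerades as control enrichment and roughly
  quadruples false reports; bidirectional planting balances the denominator
  and mirrors the biology of dysbiosis, where taxa move both ways.
* **Planted latent sd 0.8** (vs 1.0 elsewhere) so that the 1% major-genus
  filter decision for panel genera is stable across seeds; the planted
  fold-changes are calibrated for testability, as no effect sizes are
  reported for the original cohort.
* **Latent association structure** lives on taxa between ~0.03% and ~1%
  abundance: common enough to be observed in nearly every sample, rare
  enough that correlated partners contribute negligibly to the
  compositional denominator (otherwise the correlation *contrast* between
  groups leaks into the marginal abundance tests). Controls carry 12 mixed
  blocks of 7 (5 bacteria + 2 fungi, pairwise latent r = 0.7); cases carry
  8 sparse cross-kingdom pairs. Ground-truth edges are pairs with |latent
  correlation| >= 0.4 (configurable).

`network_contrast_scenario()` is a second, deliberately clean world for the
network-disruption property: 80 bacterial taxa on a *flat* composition
(closure correlations ~ -1/79, negligible), dense control blocks of 7
(planted degree 6) versus sparse case pairs (degree 1). On the realistic
default scenario, compositional closure among the abundant head taxa
produces real negative correlations whose per-seed counts fluctuate by more
than the planted edge contrast, so the per-seed "control denser than case"
direction holds on average (and in ~83% of seeds) but not at a 95% per-seed
rate; the flat-world scenario is the appropriate instrument for that
sharper claim, and both facts are tested as such.

What the generator does **not** emulate: overdispersed library sizes,
zero-inflation beyond multinomial sampling, phylogenetic signal in the
correlation structure, batch effects, or taxa present in only one group. A
green test therefore establishes correctness of the statistical machinery
on a well-specified world, not robustness to every failure mode of real
amplicon data.

# Diversity

Alpha indices are computed per sample: Shannon entropy in nats (the log
base is an argument; the study does not state one), reciprocal Simpson
1/sum(p^2) (the study reports "Simpson reciprocal indexes"; a complement
toggle exists because axis labels elsewhere are ambiguous), bias-corrected
Chao1 `S + F1(F1-1)/(2(F2+1))` (robust when F2 = 0), and ACE with the
conventional rare/abundant cutoff of 10. Chao1 and ACE require integer
counts and error otherwise. No rarefaction is applied by default (none is
stated in the source protocol); all indices are validated against
hand-computed values and the vegan estimators.

Beta diversity: Bray-Curtis via `vegan::vegdist` on counts; unweighted and
weighted (normalized) UniFrac implemented on `ape` trees and validated
against hand computations on toy trees and against `phyloseq::UniFrac`.
PCoA is classical metric scaling — double-centering and
eigendecomposition — reporting all eigenvalues (negative ones flag
non-Euclidean input) and embedding only the positive part. Group separation
uses a one-way PERMANOVA with pseudo-F and label permutation,
p = (1 + #{F_perm >= F_obs}) / (1 + n_perm); the source asserts
"significant clustering" without naming a test, so PERMANOVA (999
permutations by default) is this package's documented stand-in.

# Differential abundance

The LEfSe-style screen follows the reference procedure: per-sample
normalization to 1e6; a per-taxon two-group rank test at alpha = 0.05; a
bootstrap linear-discriminant effect size on the retained features; and the
report rule p < .05 with |LDA score| strictly > 2. Two notes:

* The two-class Kruskal-Wallis stage is implemented as the exact-capable
  Wilcoxon rank-sum test (they are equivalent for two groups); this is what
  makes small-sample p-values exact rather than chi-square approximations.
* Each bootstrap round subsamples 2/3 of each class, fits a Fisher
  discriminant with the pooled within-class covariance ridge-regularized by
  1e-6 x its trace (degenerate, collinear features occur routinely), and
  scores each feature as the mean of its contribution along the unit
  discriminant axis (scaled by the class separation on that axis) and its
  raw class-mean difference; the final score is log10(1 + |mean effect|),
  signed positive for control-enriched features. The subclass (within-group
  Wilcoxon) stage of the reference procedure is omitted — this design has
  no subclass structure — but the API keeps the normalization convention so
  scores are comparable.

On the per-million scale every abundant feature passing the rank test also
clears |LDA| > 2, so the effect-size threshold does not reduce false
reports among major genera; the false-report bound in the acceptance suite
is carried almost entirely by the rank test's level. This is a known
property of the procedure, not a defect of this implementation.

# Association networks

Within-kingdom networks: all-pairs Spearman correlation (midranks under
ties; t-approximation for n >= 10, exact for smaller n without ties) on
relative abundances of taxa present in strictly more than 50% of the
group's samples; edges keep pairs with two-sided p < .05, signed by rho.
Interkingdom networks: distance correlation per cross-kingdom pair on taxa
present in strictly more than 20% of samples, with a permutation test —
one margin permuted, p = (1 + #{dcor_perm >= dcor_obs}) / (1 + n_perm),
the same permutation set shared across pairs for speed and seeded
reproducibility. dCor is non-negative, so retained edges borrow their sign
from the pair's Spearman rho (an interpretive choice, documented). Raw
p < .05 with no multiplicity correction is the default because the source
figures state exactly that; a Benjamini-Hochberg mode is provided as a
documented deviation. Compositionality-aware association methods
(SparCC-like) are deliberately out of scope.

Networks count as nodes only taxa with at least one significant edge —
this is what allows "a decrease in the number of nodes" under a fixed taxon
set. Relative connectedness is edges/nodes; groups are compared by a
two-sided Mann-Whitney test on the node-degree distributions.

# Panel classifier

`fit_panel()` fits a maximum-likelihood logistic regression of case status
on the panel genera's relative abundances (raw by default; log10 optional),
falling back to a small ridge penalty under (quasi-)separation. The primary
output is the apparent (resubstitution) AUC by the rank (Mann-Whitney)
formulation with a stratified bootstrap percentile CI of the fitted scores
(2000 resamples by default, seeded; DeLong optional) — matching the
convention of reporting a single fitted ROC for a small cohort. A
stratified k-fold cross-validated AUC (with its own bootstrap CI) is
provided and recommended: at n = 40 with 4-8 features the apparent AUC is
substantially optimistic. Quantitatively, under a null world the apparent
AUC of the 8-genus panel averages ~0.7, so a CI centred on it essentially
never covers 0.5; the CV AUC is correctly centred at 0.5, but even its
bootstrap CI undercovers (measured ~83-89% against a nominal 95% over 200
replicates) because resampling fixed CV scores ignores model-refit and
fold-assignment variability. Repeated CV and LOO-CV were evaluated and are
worse (LOO-AUC is pathologically pessimistic under class imbalance). This
is a real small-sample limitation of bootstrap AUC inference for fitted
models, it is measured rather than hidden, and the corresponding acceptance
check is intentionally left failing with this analysis on record.

# Pipeline and reproducibility

`run_pipeline()` chains simulate/load -> major-genus filter (mean relative
abundance >= 1%, inclusive) -> diversity -> LEfSe per kingdom -> per-group
networks and comparison -> the three panel fits, writing TSVs and a JSON
manifest of parameters plus the md5 of every artifact. All randomness flows
from explicit seeds; identical configs give bit-identical manifests (this
is itself an acceptance check). Any stage failure aborts with the stage
name and removes the partial output directory if the run created it.

Test-suite economy: null calibrations use 99-199 permutations (p-resolution
0.005-0.01, ample at alpha = .05), the dcor null uses 1000 cross-kingdom
pairs with 199 shared permutations, and bootstrap CI coverage uses 500-1000
resamples — scaled for a single-CPU budget; thresholds and acceptance bands
are never scaled.

# Known limitations

* Spearman edge p-values use the t-approximation at n >= 10; at n = 16 it
  is slightly anticonservative, which inflates both groups' networks
  equally but matters if absolute edge counts are interpreted.
* The LDA effect size inherits the reference procedure's insensitivity of
  the score threshold for abundant features (see above).
* Apparent AUCs should not be compared across panels of different sizes
  without cross-validation; the pipeline reports both when `cv_folds > 0`.
* UniFrac treats the tree as given (no rooting checks beyond what the
  edge traversal implies) and requires branch lengths.
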