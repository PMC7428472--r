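#' Build a block-diagonal equicorrelation matrix
#'
#' Utility for declaring latent association structure: every pair of taxa
#' inside one block gets correlation `rho`, everything else 0.  Equicorrelated
#' blocks are positive semi-definite whenever `rho >= -1/(k-1)` for block size
#' k, so planted structure built this way is always a valid correlation matrix.
#'
#' @param n total number of taxa
#' @param blocks list of integer index vectors (disjoint)
#' @param rho within-block correlation
#' @return an n x n correlation matrix
#' @export
block_correlation <- function(n, blocks = list(), rho = 0.7) {
  C <- diag(n)
  seen <- integer(0)
  for (b in blocks) {
    if (any(b %in% seen)) stop("blocks must be disjoint")
    seen <- c(seen, b)
    C[b, b] <- rho
    diag(C)[b] <- 1
  }
  C
}

#' Declare a two-kingdom simulation scenario
#'
#' Fixes everything the generator needs: group sizes, taxon counts per
#' kingdom, sequencing-depth range, planted differentially abundant taxa
#' (latent log2 fold-changes), and one latent correlation matrix per group
#' spanning *all* taxa of both kingdoms (cross-kingdom entries are what the
#' interkingdom network should recover).
#'
#' @param n_group1,n_group2 samples per group (>= 3 each)
#' @param n_bact_taxa,n_fungi_taxa taxa per kingdom
#' @param depth_range length-2 integer vector, reads per sample drawn
#'   uniformly from this range (per kingdom)
#' @param diff_taxa data.frame with columns `taxon`, `kingdom`, `log2fc`,
#'   `group` (the enriched group label)
#' @param latent_corr_group1,latent_corr_group2 correlation matrices over the
#'   `n_bact_taxa + n_fungi_taxa` taxa (bacteria first)
#' @param base_log_abundance per-taxon mean on the latent log scale
#' @param latent_sd per-taxon latent standard deviation (recycled)
#' @param group_labels labels for the two groups
#' @param taxon_names optional character vector of taxon ids (bacteria first)
#' @param edge_threshold |latent correlation| at or above which a taxon pair
#'   counts as a ground-truth edge
#' @param seed integer seed
#' @return a validated `scenario_config`
#' @export
scenario_config <- function(n_group1, n_group2, n_bact_taxa, n_fungi_taxa,
                            depth_range = c(10000L, 40000L),
                            diff_taxa = NULL,
                            latent_corr_group1 = NULL,
                            latent_corr_group2 = NULL,
                            base_log_abundance = NULL,
                            latent_sd = 1,
                            group_labels = c("group1", "group2"),
                            taxon_names = NULL,
                            edge_threshold = 0.4,
                            seed = 1L) {
  p <- n_bact_taxa + n_fungi_taxa
  if (n_group1 < 3 || n_group2 < 3)
    stop("each group needs at least 3 samples (rank tests undefined below)")
  if (length(depth_range) != 2 || depth_range[1] > depth_range[2] ||
      any(depth_range <= 0))
    stop("depth_range must be a positive pair low <= high")
  if (is.null(latent_corr_group1)) latent_corr_group1 <- diag(p)
  if (is.null(latent_corr_group2)) latent_corr_group2 <- diag(p)
  for (nm in c("latent_corr_group1", "latent_corr_group2")) {
    C <- get(nm)
    if (!isSymmetric(unname(C), tol = 1e-8))
      stop(nm, " is not symmetric")
    if (max(abs(diag(C) - 1)) > 1e-8)
      stop(nm, " must have a unit diagonal")
    ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8)
      stop(nm, " is not positive semi-definite (smallest eigenvalue ",
           format(ev, digits = 4), ")")
  }
  if (is.null(taxon_names))
    taxon_names <- c(sprintf("Bact_g%03d", seq_len(n_bact_taxa)),
                     sprintf("Fungi_g%03d", seq_len(n_fungi_taxa)))
  if (length(taxon_names) != p || anyDuplicated(taxon_names))
    stop("taxon_names must be ", p, " unique ids")
  if (is.null(base_log_abundance)) base_log_abundance <- rep(0, p)
  if (length(base_log_abundance) != p)
    stop("base_log_abundance must have length ", p)
  latent_sd <- rep_len(latent_sd, p)
  if (is.null(diff_taxa))
    diff_taxa <- data.frame(taxon = character(), kingdom = character(),
                            log2fc = numeric(), group = character(),
                            stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "kingdom", "log2fc", "group") %in% names(diff_taxa)))
  if (!all(diff_taxa$taxon %in% taxon_names))
    stop("diff_taxa refer to unknown taxa: ",
         paste(setdiff(diff_taxa$taxon, taxon_names), collapse = ", "))
  if (!all(is.finite(diff_taxa$log2fc)))
    stop("fold-changes must be finite")
  if (!all(diff_taxa$group %in% group_labels))
    stop("diff_taxa groups must be among the group labels")
  structure(list(
    n_group1 = as.integer(n_group1), n_group2 = as.integer(n_group2),
    n_bact_taxa = as.integer(n_bact_taxa),
    n_fungi_taxa = as.integer(n_fungi_taxa),
    depth_range = as.integer(depth_range), diff_taxa = diff_taxa,
    latent_corr_group1 = latent_corr_group1,
    latent_corr_group2 = latent_corr_group2,
    base_log_abundance = base_log_abundance, latent_sd = latent_sd,
    group_labels = group_labels, taxon_names = taxon_names,
    edge_threshold = edge_threshold, seed = as.integer(seed)),
    class = "scenario_config")
}

## symmetric square root via eigendecomposition; tolerant of PSD-singular input
.corr_sqrt <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

.latent_edges <- function(C, names, threshold) {
  idx <- which(abs(C) >= threshold & upper.tri(C), arr.ind = TRUE)
  data.frame(taxon_a = names[idx[, 1]], taxon_b = names[idx[, 2]],
             corr = C[idx], stringsAsFactors = FALSE)
}

#' Simulate two-kingdom count tables with known ground truth
#'
#' The generative model is a Gaussian copula on log abundances: each sample's
#' latent vector is multivariate normal with the group's correlation matrix;
#' planted log2 fold-changes (times ln 2) are added to the latent means of the
#' enriched group; the vector is exponentiated and normalized to a composition
#' *within each kingdom*; counts are drawn multinomially at a library depth
#' drawn uniformly from `depth_range`.
#'
#' @param config a [scenario_config()]
#' @param seed optional override of `config$seed`
#' @return list with `bact` and `fungi` abundance tables, `meta` (sample_id,
#'   group), and `truth` (planted `diff_taxa`, per-group latent `edges` at
#'   `edge_threshold`, and per-group true `connectedness` = edges / nodes)
#' @export
simulate_tables <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  p <- config$n_bact_taxa + config$n_fungi_taxa
  nm <- config$taxon_names
  is_bact <- seq_len(p) <= config$n_bact_taxa
  n <- c(config$n_group1, config$n_group2)
  shift <- matrix(0, 2, p, dimnames = list(config$group_labels, nm))
  if (nrow(config$diff_taxa))
    for (i in seq_len(nrow(config$diff_taxa)))
      shift[config$diff_taxa$group[i], config$diff_taxa$taxon[i]] <-
        shift[config$diff_taxa$group[i], config$diff_taxa$taxon[i]] +
        config$diff_taxa$log2fc[i] * log(2)
  L <- list(.corr_sqrt(config$latent_corr_group1),
            .corr_sqrt(config$latent_corr_group2))
  counts <- matrix(0, sum(n), p,
                   dimnames = list(sprintf("S%03d", seq_len(sum(n))), nm))
  group <- rep(config$group_labels, n)
  row <- 0L
  for (g in 1:2) {
    Z <- matrix(stats::rnorm(n[g] * p), n[g], p) %*% t(L[[g]])
    latent <- sweep(Z, 2, config$latent_sd, `*`)
    latent <- sweep(latent, 2, config$base_log_abundance + shift[g, ], `+`)
    for (i in seq_len(n[g])) {
      row <- row + 1L
      for (king in list(which(is_bact), which(!is_bact))) {
        if (!length(king)) next
        w <- exp(latent[i, king])
        depth <- sample(config$depth_range[1]:config$depth_range[2], 1L)
        counts[row, king] <- stats::rmultinom(1, depth, w / sum(w))
      }
    }
  }
  meta <- data.frame(sample_id = rownames(counts),
                     group = factor(group, levels = config$group_labels),
                     stringsAsFactors = FALSE)
  truth <- list(
    diff_taxa = config$diff_taxa,
    edges = list(
      .latent_edges(config$latent_corr_group1, nm, config$edge_threshold),
      .latent_edges(config$latent_corr_group2, nm, config$edge_threshold)))
  names(truth$edges) <- config$group_labels
  truth$connectedness <- vapply(truth$edges, function(e) {
    nodes <- length(unique(c(e$taxon_a, e$taxon_b)))
    if (nodes == 0) 0 else nrow(e) / nodes
  }, numeric(1))
  tax_b <- stats::setNames(
    sprintf("k__Bacteria; p__Unknown; f__Unknown; g__%s", nm[is_bact]),
    nm[is_bact])
  tax_f <- stats::setNames(
    sprintf("k__Fungi; p__Unknown; f__Unknown; g__%s", nm[!is_bact]),
    nm[!is_bact])
  list(bact = abundance_table(counts[, is_bact, drop = FALSE], "bacteria",
                              tax_b),
       fungi = abundance_table(counts[, !is_bact, drop = FALSE], "fungi",
                               tax_f),
       meta = meta, truth = truth)
}

#' The default case-control scenario
#'
#' Emulates a two-kingdom depressive-episode case-control design: 24 cases
#' (CDE) vs 16 healthy controls (HC), 100 bacterial and 60 fungal genera,
#' four planted case-enriched genera per kingdom (the classifier panel:
#' Akkermansia, Clostridium_sensu_stricto_1, UBA1819, Veillonella;
#' Candida, Chaetomium, Neocosmospora, Occultifur) plus four planted
#' control-enriched genera per kingdom (Dialister, Fusicatenibacter,
#' Lachnospira, Sutterella; Scedosporium, Purpureocillium, Penicillium,
#' Aureobasidium), all at a latent log2 fold-change of 2, and a *denser*
#' latent association structure in the control group (mixed within- and
#' cross-kingdom blocks at rho = 0.7) against a sparse paired structure in
#' cases — so control networks should show higher relative connectedness,
#' as the dysbiosis analysis expects.
#'
#' @param seed integer seed stored in the config
#' @return a [scenario_config()]
#' @export
default_paper_like_scenario <- function(seed = 1L) {
  n_b <- 100L; n_f <- 60L; p <- n_b + n_f
  bact_panel <- c("Akkermansia", "Clostridium_sensu_stricto_1",
                  "UBA1819", "Veillonella")
  fungi_panel <- c("Candida", "Chaetomium", "Neocosmospora", "Occultifur")
  ## control-enriched genera, mirroring the study's decreased-in-cases taxa;
  ## planting effects in BOTH directions keeps the composition balanced so
  ## the one-sided panel enrichment does not depress every null taxon in
  ## cases (which would masquerade as control enrichment)
  bact_down <- c("Dialister", "Fusicatenibacter", "Lachnospira", "Sutterella")
  fungi_down <- c("Scedosporium", "Purpureocillium", "Penicillium",
                  "Aureobasidium")
  nm <- c(bact_panel, bact_down, sprintf("Bact_g%03d", seq_len(n_b - 8L)),
          fungi_panel, fungi_down, sprintf("Fungi_g%03d", seq_len(n_f - 8L)))
  ## Rank-abundance shape mimics real stool genus tables: a steep abundant
  ## head (the "major genera": ~9 null + 8 planted bacterial, ~6 null + 8
  ## planted fungal at >= 1% mean relative abundance) over a long sub-1%
  ## tail.  Planted genera sit just below 1% in their depleted group and
  ## cross the major-genus filter through their enriched group; their latent
  ## sd is 0.8 (vs 1 elsewhere) so the filter decision is stable across
  ## seeds.  Planted effects are calibrated for testability, not fidelity:
  ## the source study reports no effect sizes.
  base <- c(rep(1.5, 4), rep(1.8, 4),          # planted bacteria (CDE / HC)
            seq(4.8, 3.0, length.out = 9),     # abundant head
            seq(1.7, -2.8, length.out = 83),   # tail
            rep(1.4, 4), rep(1.6, 4),          # planted fungi (CDE / HC)
            seq(5.0, 3.4, length.out = 4),
            seq(1.5, -2.6, length.out = 48))
  latent_sd <- c(rep(0.8, 8), rep(1, 92), rep(0.8, 8), rep(1, 52))
  diff_taxa <- data.frame(
    taxon = c(bact_panel, bact_down, fungi_panel, fungi_down),
    kingdom = rep(c("bacteria", "fungi"), each = 8),
    log2fc = 2,
    group = rep(c("CDE", "HC", "CDE", "HC"), each = 4),
    stringsAsFactors = FALSE)
  ## Latent association structure lives in the upper tail (0.03-1% taxa):
  ## abundant enough to be observed in nearly every sample, rare enough that
  ## correlated partners contribute negligibly to the compositional
  ## denominator (so the correlation contrast does not masquerade as
  ## differential abundance).  Controls get 12 mixed blocks of 7 (5 bacteria
  ## + 2 fungi): 120 bacteria-bacteria, 120 cross-kingdom and 12
  ## fungus-fungus latent edges; cases get 8 sparse cross-kingdom pairs.
  bact_pool <- 19:80    # bacterial tail positions 2..63
  fungi_pool <- 113:144 # fungal tail positions 1..32
  hc_blocks <- lapply(1:12, function(k)
    c(bact_pool[((k - 1) * 5 + 1):((k - 1) * 5 + 5)],
      fungi_pool[((k - 1) * 2 + 1):((k - 1) * 2 + 2)]))
  cde_blocks <- lapply(1:8, function(k)
    c(bact_pool[19 + k], fungi_pool[9 + k]))
  scenario_config(
    n_group1 = 24L, n_group2 = 16L, n_bact_taxa = n_b, n_fungi_taxa = n_f,
    depth_range = c(10000L, 40000L), diff_taxa = diff_taxa,
    latent_corr_group1 = block_correlation(p, cde_blocks, 0.7),
    latent_corr_group2 = block_correlation(p, hc_blocks, 0.7),
    base_log_abundance = base, latent_sd = latent_sd,
    group_labels = c("CDE", "HC"), taxon_names = nm,
    edge_threshold = 0.4, seed = seed)
}

#' A dense-vs-sparse network-contrast scenario
#'
#' A scenario purpose-built for studying network-disruption recovery:
#' 80 bacterial taxa on a *flat* composition (so compositional-closure
#' correlations are negligible and edge discovery is near its nominal
#' level), with a dense latent structure in the control group (10
#' equicorrelated blocks of 7 at rho = 0.7; planted node degree 6) against
#' a sparse structure in cases (15 disjoint pairs; planted degree 1) — a
#' planted mean-degree ratio of 6 over more than 30 participating nodes.
#' Ten uncorrelated fungal taxa are included so the two-kingdom plumbing
#' stays exercised.
#'
#' @param seed integer seed stored in the config
#' @return a [scenario_config()]
#' @export
network_contrast_scenario <- function(seed = 1L) {
  n_b <- 80L; n_f <- 10L; p <- n_b + n_f
  dense_blocks <- lapply(1:10, function(k) ((k - 1) * 7 + 1):((k - 1) * 7 + 7))
  sparse_blocks <- lapply(1:15, function(k) c(2 * k - 1, 2 * k))
  scenario_config(
    n_group1 = 24L, n_group2 = 16L, n_bact_taxa = n_b, n_fungi_taxa = n_f,
    depth_range = c(20000L, 40000L),
    latent_corr_group1 = block_correlation(p, sparse_blocks, 0.7),
    latent_corr_group2 = block_correlation(p, dense_blocks, 0.7),
    base_log_abundance = rep(0, p), latent_sd = 1,
    group_labels = c("case", "control"), edge_threshold = 0.4, seed = seed)
}

#' Write a simulated dataset to a directory
#'
#' Emits the standard on-disk layout: `bacteria.tsv` / `fungi.tsv` abundance
#' tables (taxa x samples), matching taxonomy TSVs, and `metadata.tsv` with a
#' `group` column; optionally BIOM copies.
#'
#' @param sim result of [simulate_tables()]
#' @param dir output directory (created if missing)
#' @param biom also write BIOM-format copies (needs biomformat)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir, biom = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(sim$bact, file.path(dir, "bacteria.tsv"),
              taxonomy_path = file.path(dir, "bacteria_taxonomy.tsv"))
  write_table(sim$fungi, file.path(dir, "fungi.tsv"),
              taxonomy_path = file.path(dir, "fungi_taxonomy.tsv"))
  utils::write.table(sim$meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (biom) {
    write_table(sim$bact, file.path(dir, "bacteria.biom"), format = "biom")
    write_table(sim$fungi, file.path(dir, "fungi.biom"), format = "biom")
  }
  invisible(dir)
}
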