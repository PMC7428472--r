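# shared fixture builders; everything is generated in code under fixed seeds

# abundance_table from a bare matrix, auto-labelling samples/taxa
make_at <- function(m, kingdom = "bacteria", taxonomy = NULL) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("T%02d", seq_len(ncol(m)))
  abundance_table(m, kingdom, taxonomy)
}

# exchangeable null world: flat composition, no correlation, no effects
null_scenario <- function(n1 = 20, n2 = 20, n_bact = 30, n_fungi = 20,
                          depth = c(20000L, 40000L), seed = 1L) {
  scenario_config(n_group1 = n1, n_group2 = n2, n_bact_taxa = n_bact,
                  n_fungi_taxa = n_fungi, depth_range = depth, seed = seed)
}

# the default case-control scenario with all effects and the correlation
# contrast switched off (groups fully exchangeable, panel genera kept)
nulled_default_scenario <- function(seed = 1L) {
  sc <- default_paper_like_scenario(seed)
  sc$diff_taxa$log2fc <- 0
  sc$latent_corr_group2 <- sc$latent_corr_group1
  sc
}

# group-subset of an abundance table
group_subset <- function(tb, idx) {
  abundance_table(tb$counts[idx, , drop = FALSE], tb$kingdom, tb$taxonomy)
}

panel_genera_bact <- c("Akkermansia", "Clostridium_sensu_stricto_1",
                       "UBA1819", "Veillonella")
panel_genera_fungi <- c("Candida", "Chaetomium", "Neocosmospora",
                        "Occultifur")
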