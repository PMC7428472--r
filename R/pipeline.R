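#' Assemble a pipeline configuration
#'
#' One validated object carries every knob of the end-to-end analysis:
#' either a simulation scenario or paths to on-disk tables, the filtering
#' thresholds, permutation counts, and explicit seeds (no hidden entropy).
#'
#' @param scenario a [scenario_config()] to simulate from, or `NULL` when
#'   loading from disk
#' @param bact_table,fungi_table,metadata,tree file paths (used when
#'   `scenario` is `NULL`; `tree` optional, enables UniFrac)
#' @param major_genus_threshold mean relative-abundance cut (default 0.01)
#' @param prevalence_bacterial within-kingdom network prevalence (default 0.5)
#' @param prevalence_interkingdom interkingdom network prevalence (default 0.2)
#' @param alpha significance threshold used throughout (default 0.05)
#' @param lda_threshold LEfSe report cut (default 2.0)
#' @param n_perm permutations for PERMANOVA and dcor edges
#' @param n_boot_lda LEfSe bootstrap rounds
#' @param n_boot_auc bootstrap resamples for the AUC CI
#' @param cv_folds cross-validation folds for the classifier (0 = off)
#' @param networks `"both"`, `"bacteria"`, or `"interkingdom"`
#' @param seed master seed
#' @return validated list of class `pipeline_config`
#' @export
pipeline_config <- function(scenario = NULL, bact_table = NULL,
                            fungi_table = NULL, metadata = NULL, tree = NULL,
                            major_genus_threshold = 0.01,
                            prevalence_bacterial = 0.5,
                            prevalence_interkingdom = 0.2,
                            alpha = 0.05, lda_threshold = 2.0,
                            n_perm = 999, n_boot_lda = 30,
                            n_boot_auc = 2000, cv_folds = 0,
                            networks = c("both", "bacteria", "interkingdom"),
                            seed = 1L) {
  networks <- match.arg(networks)
  chk01 <- function(v, nm) if (v <= 0 || v >= 1)
    stop(nm, " must lie strictly inside (0, 1)")
  chk01(major_genus_threshold, "major_genus_threshold")
  chk01(prevalence_bacterial, "prevalence_bacterial")
  chk01(prevalence_interkingdom, "prevalence_interkingdom")
  chk01(alpha, "alpha")
  if (lda_threshold < 0) stop("lda_threshold must be >= 0")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(scenario)) {
    for (nm in c("bact_table", "fungi_table", "metadata")) {
      v <- get(nm)
      if (is.null(v))
        stop("without a scenario, '", nm, "' is required")
      if (!file.exists(v))
        stop(nm, " file not found: ", v)
    }
    if (!is.null(tree) && !file.exists(tree))
      stop("tree file not found: ", tree)
  } else stopifnot(inherits(scenario, "scenario_config"))
  structure(list(scenario = scenario, bact_table = bact_table,
                 fungi_table = fungi_table, metadata = metadata, tree = tree,
                 major_genus_threshold = major_genus_threshold,
                 prevalence_bacterial = prevalence_bacterial,
                 prevalence_interkingdom = prevalence_interkingdom,
                 alpha = alpha, lda_threshold = lda_threshold,
                 n_perm = n_perm, n_boot_lda = n_boot_lda,
                 n_boot_auc = n_boot_auc, cv_folds = cv_folds,
                 networks = networks, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Flat JSON mirroring [pipeline_config()] arguments; a `"scenario":
#' "default"` entry selects [default_paper_like_scenario()].
#'
#' @param path JSON file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(cfg$scenario, "default"))
    cfg$scenario <- default_paper_like_scenario(
      seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
  do.call(pipeline_config, cfg)
}

.stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  log(sprintf("stage %-14s done in %.2fs", name,
              as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) two-kingdom tables, filter to major genera, compute
#' alpha diversity with group tests, Bray-Curtis (plus UniFrac when a tree is
#' available) beta diversity with PCoA and PERMANOVA, LEfSe differential
#' abundance per kingdom, per-group within-kingdom and interkingdom
#' association networks with comparisons, and the three genus-panel
#' classifiers.  All outputs are written as TSV under `out_dir` together
#' with a deterministic JSON run manifest (parameters + md5 of every
#' artifact); identical configs produce identical manifests.  On any stage
#' failure the partial output directory is removed (if this run created it).
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory
#' @param quiet suppress progress logging to stderr
#' @return (invisibly) list with all stage results and `manifest`
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- if (quiet) function(...) invisible() else
    function(msg) message("[mycobnet] ", msg)
  on_fail <- function(e) {
    if (created) unlink(out_dir, recursive = TRUE)
    stop(e)
  }
  tryCatch(run_pipeline_impl(config, out_dir, log), error = on_fail)
}

run_pipeline_impl <- function(config, out_dir, log) {
  seed <- config$seed
  out <- function(...) file.path(out_dir, ...)
  tsv <- function(df, name) {
    utils::write.table(df, out(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    name
  }
  files <- character()

  ## ---- input ----
  dat <- .stage("input", log, {
    if (!is.null(config$scenario)) {
      simulate_tables(config$scenario, seed = seed)
    } else {
      bact <- read_table(config$bact_table, "tsv", "bacteria")
      fungi <- read_table(config$fungi_table, "tsv", "fungi")
      meta <- read_metadata(config$metadata)
      c(align_kingdoms(bact, fungi, meta), list(truth = NULL))
    }
  })
  tree <- if (!is.null(config$tree)) ape::read.tree(config$tree) else NULL
  groups <- dat$meta$group

  ## ---- filtering ----
  filt <- .stage("filter", log, list(
    bact = filter_major_genera(dat$bact, config$major_genus_threshold),
    fungi = filter_major_genera(dat$fungi, config$major_genus_threshold)))

  ## ---- alpha diversity ----
  alpha_res <- .stage("alpha", log, lapply(dat[c("bact", "fungi")],
                                           function(tb) {
    a <- alpha_indices(tb)
    list(values = a, p = compare_alpha(a[-1], groups))
  }))
  for (k in names(alpha_res)) {
    files <- c(files, tsv(alpha_res[[k]]$values, paste0("alpha_", k, ".tsv")))
    files <- c(files, tsv(data.frame(index = names(alpha_res[[k]]$p),
                                     p_value = unname(alpha_res[[k]]$p)),
                          paste0("alpha_", k, "_tests.tsv")))
  }

  ## ---- beta diversity ----
  beta_res <- .stage("beta", log, lapply(dat[c("bact", "fungi")],
                                         function(tb) {
    metrics <- c("bray_curtis",
                 if (!is.null(tree) &&
                     all(taxon_ids(tb) %in% tree$tip.label))
                   c("unweighted_unifrac", "weighted_unifrac"))
    stats::setNames(lapply(metrics, function(mt)
      beta_diversity(tb, mt, tree = tree, groups = groups,
                     n_perm = config$n_perm, seed = seed)), metrics)
  }))
  for (k in names(beta_res)) for (mt in names(beta_res[[k]])) {
    b <- beta_res[[k]][[mt]]
    D <- as.matrix(b$distance)
    files <- c(files,
               tsv(data.frame(sample_id = rownames(D), D,
                              check.names = FALSE),
                   paste0("beta_", k, "_", mt, ".tsv")),
               tsv(data.frame(sample_id = rownames(b$pcoa$coordinates),
                              b$pcoa$coordinates[, seq_len(
                                min(3, ncol(b$pcoa$coordinates))),
                                drop = FALSE], check.names = FALSE),
                   paste0("pcoa_", k, "_", mt, ".tsv")))
  }

  ## ---- differential abundance ----
  lefse_res <- .stage("lefse", log, lapply(filt, function(tb)
    lefse(tb, groups, alpha = config$alpha,
          lda_threshold = config$lda_threshold, n_boot = config$n_boot_lda,
          seed = seed)))
  for (k in names(lefse_res)) {
    write_lefse_report(lefse_res[[k]], out(paste0("lefse_", k, ".tsv")))
    files <- c(files, paste0("lefse_", k, ".tsv"))
  }

  ## ---- networks ----
  nets <- .stage("networks", log, {
    res <- list()
    split_idx <- split(seq_along(groups), groups)
    sub <- function(tb, idx) at_replace(tb, tb$counts[idx, , drop = FALSE])
    if (config$networks %in% c("both", "bacteria")) {
      res$bacterial <- lapply(names(split_idx), function(g)
        build_spearman_network(sub(dat$bact, split_idx[[g]]), g,
                               prevalence = config$prevalence_bacterial,
                               alpha = config$alpha))
      names(res$bacterial) <- names(split_idx)
      res$bacterial_comparison <-
        compare_networks(res$bacterial[[1]], res$bacterial[[2]])
    }
    if (config$networks %in% c("both", "interkingdom")) {
      res$interkingdom <- lapply(names(split_idx), function(g)
        build_interkingdom_network(
          sub(dat$bact, split_idx[[g]]), sub(dat$fungi, split_idx[[g]]), g,
          prevalence = config$prevalence_interkingdom,
          alpha = config$alpha, n_perm = config$n_perm, seed = seed))
      names(res$interkingdom) <- names(split_idx)
      res$interkingdom_comparison <-
        compare_networks(res$interkingdom[[1]], res$interkingdom[[2]])
    }
    res
  })
  for (kind in intersect(c("bacterial", "interkingdom"), names(nets))) {
    for (g in names(nets[[kind]])) {
      nm <- paste0("network_", kind, "_", g, ".tsv")
      write_edge_list(nets[[kind]][[g]], out(nm))
      files <- c(files, nm)
    }
    files <- c(files, tsv(nets[[paste0(kind, "_comparison")]],
                          paste0("network_", kind, "_comparison.tsv")))
  }

  ## ---- classifier ----
  cls <- .stage("classifier", log, {
    fits <- lapply(c("bacterial4", "fungal4", "combined8"), function(p)
      fit_panel(dat$bact, dat$fungi, dat$meta, genus_panel(p),
                case_group = levels(groups)[1], n_boot = config$n_boot_auc,
                cv_folds = config$cv_folds, seed = seed))
    names(fits) <- c("bacterial4", "fungal4", "combined8")
    list(fits = fits, summary = compare_panels(fits))
  })
  files <- c(files, tsv(cls$summary, "classifier_summary.tsv"))
  for (p in names(cls$fits))
    files <- c(files, tsv(roc_points(cls$fits[[p]]$scores,
                                     cls$fits[[p]]$labels),
                          paste0("roc_", p, ".tsv")))

  ## ---- manifest ----
  manifest <- .stage("manifest", log, {
    params <- config[setdiff(names(config), "scenario")]
    params <- params[!vapply(params, is.null, logical(1))]
    man <- list(
      package = "mycobnet",
      version = as.character(utils::packageVersion("mycobnet")),
      seed = seed,
      parameters = params[order(names(params))],
      scenario_hash = if (!is.null(config$scenario))
        digest_obj(config$scenario) else NA,
      outputs = lapply(stats::setNames(sort(files), sort(files)),
                       function(f) unname(tools::md5sum(out(f)))))
    jsonlite::write_json(man, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    man
  })
  invisible(list(data = dat, filtered = filt, alpha = alpha_res,
                 beta = beta_res, lefse = lefse_res, networks = nets,
                 classifier = cls, manifest = manifest,
                 manifest_hash = unname(tools::md5sum(out("manifest.json")))))
}

## stable md5 of an R object via its serialized ASCII form
digest_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "w")
  dput(x, con)
  close(con)
  unname(tools::md5sum(f))
}
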