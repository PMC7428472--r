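#' Scale each sample to one million
#'
#' The conventional normalization preceding LDA effect-size scoring: every
#' sample's abundances are rescaled to sum to 1e6, so effect sizes live on a
#' comparable per-million scale and log10 scores around 2-6 are meaningful.
#'
#' @param x an `abundance_table`
#' @return an `abundance_table` whose rows each sum to 1e6
#' @export
normalize_for_lefse <- function(x) {
  tot <- rowSums(x$counts)
  zero <- which(tot <= 0)
  if (length(zero))
    stop("zero-sum sample(s): ", paste(sample_ids(x)[zero], collapse = ", "))
  at_replace(x, x$counts / tot * 1e6)
}

#' Stage-1 rank-test screen
#'
#' Per-taxon two-sided rank-sum test between the two groups (the two-class
#' specialization of the Kruskal-Wallis stage; exact when sample sizes allow
#' and there are no ties).  Constant taxa get p = 1 and are never retained.
#'
#' @param x an `abundance_table` (typically [normalize_for_lefse()] output)
#' @param groups two-level factor aligned with the samples
#' @param alpha retention threshold on the p-value (strict `<`)
#' @return data.frame `taxon`, `p_value`, `retained`
#' @export
kw_screen <- function(x, groups, alpha = 0.05) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (min(table(groups)) < 3) stop("each group needs n >= 3")
  p <- apply(x$counts, 2, rank_sum_p, groups = groups)
  data.frame(taxon = taxon_ids(x), p_value = unname(p),
             retained = unname(p) < alpha, stringsAsFactors = FALSE)
}

#' Bootstrap LDA effect size
#'
#' For each bootstrap round a class-balanced subsample (fraction
#' `boot_fraction` per class, without replacement) is drawn and a two-class
#' Fisher discriminant is fitted on the retained features (pooled within-class
#' covariance, ridge-regularized by 1e-6 x its trace on the diagonal).  Each
#' feature's round effect size is the average of (a) its contribution along
#' the unit discriminant axis scaled by the class separation on that axis and
#' (b) its raw class-mean difference.  The score is
#' `log10(1 + |mean round effect|)`, signed positive when the feature is
#' enriched in `ref_group` and negative otherwise.
#'
#' @param x an `abundance_table` restricted to the retained taxa, normalized
#'   to 1e6 per sample
#' @param groups two-level factor
#' @param ref_group the group whose enrichment is given a positive sign
#'   (default: second factor level, conventionally the control group)
#' @param n_boot bootstrap rounds
#' @param boot_fraction per-class subsample fraction
#' @param seed optional RNG seed
#' @return data.frame `taxon`, `lda_score` (signed log10), `enriched`,
#'   `mean_<group>` columns of group means
#' @export
lda_effect_size <- function(x, groups, ref_group = NULL, n_boot = 30,
                            boot_fraction = 2 / 3, seed = NULL) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (is.null(ref_group)) ref_group <- levels(groups)[2]
  if (!ref_group %in% levels(groups)) stop("unknown ref_group: ", ref_group)
  if (!is.null(seed)) set.seed(seed)
  m <- x$counts
  f <- ncol(m)
  if (f == 0)
    return(data.frame(taxon = character(), lda_score = numeric(),
                      enriched = character(), stringsAsFactors = FALSE))
  idx <- split(seq_len(nrow(m)), groups)
  sizes <- vapply(idx, function(i) as.integer(length(i) * boot_fraction),
                  integer(1))
  if (any(sizes < 3)) {
    warning("boot_fraction leaves a class below 3 samples; using 3")
    sizes <- pmax(sizes, 3L)
  }
  eff <- matrix(0, n_boot, f)
  for (b in seq_len(n_boot)) {
    s1 <- sample(idx[[1]], sizes[1])
    s2 <- sample(idx[[2]], sizes[2])
    x1 <- m[s1, , drop = FALSE]; x2 <- m[s2, , drop = FALSE]
    m1 <- colMeans(x1); m2 <- colMeans(x2)
    gm <- abs(m1 - m2)
    if (f == 1) {
      eff[b, ] <- gm
    } else {
      sw <- (stats::cov(x1) * (nrow(x1) - 1) +
               stats::cov(x2) * (nrow(x2) - 1)) / (nrow(x1) + nrow(x2) - 2)
      ridge <- 1e-6 * sum(diag(sw))
      diag(sw) <- diag(sw) + max(ridge, 1e-12)
      w <- solve(sw, m1 - m2)
      wn <- sqrt(sum(w^2))
      if (wn == 0) { eff[b, ] <- gm; next }
      w_unit <- w / wn
      ld_sep <- abs(mean(x1 %*% w_unit) - mean(x2 %*% w_unit))
      eff[b, ] <- (abs(w_unit) * ld_sep + gm) / 2
    }
  }
  mean_eff <- colMeans(eff)
  g_means <- vapply(idx, function(i) colMeans(m[i, , drop = FALSE]),
                    numeric(f))
  if (f == 1) g_means <- matrix(g_means, 1, 2,
                                dimnames = list(NULL, names(idx)))
  enriched <- colnames(g_means)[max.col(g_means)]
  score <- log10(1 + abs(mean_eff)) * ifelse(enriched == ref_group, 1, -1)
  out <- data.frame(taxon = taxon_ids(x), lda_score = score,
                    enriched = enriched, stringsAsFactors = FALSE)
  out[[paste0("mean_", colnames(g_means)[1])]] <- g_means[, 1]
  out[[paste0("mean_", colnames(g_means)[2])]] <- g_means[, 2]
  out
}

#' Filter and order differential features
#'
#' Keeps features with rank-test p < `alpha` and |LDA score| strictly greater
#' than `lda_threshold`, ordered by |score| descending.
#'
#' @param features data.frame with at least `taxon`, `p_value`, `lda_score`,
#'   `enriched`
#' @param lda_threshold log10 effect-size cut (strict `>`)
#' @param alpha p-value cut (strict `<`)
#' @return the filtered, sorted data.frame
#' @export
lefse_report <- function(features, lda_threshold = 2.0, alpha = 0.05) {
  keep <- features$p_value < alpha & abs(features$lda_score) > lda_threshold
  out <- features[keep, , drop = FALSE]
  out[order(-abs(out$lda_score)), , drop = FALSE]
}

#' LEfSe-style differential-abundance screen
#'
#' End-to-end convenience wrapper: per-sample normalization to 1e6, rank-test
#' screen at `alpha`, bootstrap LDA effect size on the retained taxa, and the
#' `|LDA| > lda_threshold` report.  Optionally repeats the analysis on
#' taxonomy-collapsed tables at additional ranks and concatenates features
#' (per-rank provenance in the `rank` column).
#'
#' @inheritParams lda_effect_size
#' @param x an `abundance_table` of counts
#' @param alpha stage-1 p-value threshold
#' @param lda_threshold report threshold on |log10 effect|
#' @param ranks optional character vector of extra taxonomy ranks to collapse
#'   to and analyse alongside the input features
#' @return data.frame of differential features: `taxon`, `rank`, `kingdom`,
#'   group means, `p_value`, `lda_score`, `enriched`
#' @export
lefse <- function(x, groups, ref_group = NULL, alpha = 0.05,
                  lda_threshold = 2.0, n_boot = 30, boot_fraction = 2 / 3,
                  seed = NULL, ranks = NULL) {
  tables <- list(input = x)
  for (r in ranks) tables[[r]] <- collapse_rank(x, r)
  res <- lapply(names(tables), function(rk) {
    tab <- normalize_for_lefse(tables[[rk]])
    screen <- kw_screen(tab, groups, alpha)
    kept <- at_replace(tab, tab$counts[, screen$retained, drop = FALSE])
    if (ncol(kept$counts) == 0) return(NULL)
    scores <- lda_effect_size(kept, groups, ref_group = ref_group,
                              n_boot = n_boot,
                              boot_fraction = boot_fraction, seed = seed)
    scores$p_value <- screen$p_value[screen$retained]
    scores$rank <- rk
    scores$kingdom <- x$kingdom
    scores
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(taxon = character(), rank = character(),
                      kingdom = character(), p_value = numeric(),
                      lda_score = numeric(), enriched = character(),
                      stringsAsFactors = FALSE))
  lefse_report(res, lda_threshold = lda_threshold, alpha = alpha)
}

#' Write a differential-feature report
#'
#' Fixed column order: taxon, rank, kingdom, enriched_group, KW_p, LDA_score.
#'
#' @param report data.frame from [lefse()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_lefse_report <- function(report, path) {
  out <- data.frame(taxon = report$taxon,
                    rank = if ("rank" %in% names(report)) report$rank else "",
                    kingdom = if ("kingdom" %in% names(report))
                      report$kingdom else "",
                    enriched_group = report$enriched,
                    KW_p = report$p_value,
                    LDA_score = report$lda_score,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
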