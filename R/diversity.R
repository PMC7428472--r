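#' Per-sample alpha-diversity indices
#'
#' Computes, for every sample: observed richness; Shannon entropy
#' \eqn{-\sum p_i \log p_i} (natural log by default); reciprocal Simpson
#' \eqn{1/\sum p_i^2} (effective number of dominant taxa); bias-corrected
#' Chao1 \eqn{S_{obs} + F_1(F_1-1)/(2(F_2+1))}; and the coverage-based ACE
#' estimator with the conventional rare/abundant cutoff of 10 reads.
#' Chao1 and ACE are richness *estimators* and require integer counts.
#'
#' @param x an `abundance_table` of counts
#' @param base logarithm base for Shannon (default natural log / nats)
#' @param simpson `"reciprocal"` (1/D, the default) or `"complement"` (1-D)
#' @return data.frame with one row per sample: `observed`, `shannon`,
#'   `simpson`, `chao1`, `ace`
#' @export
alpha_indices <- function(x, base = exp(1),
                          simpson = c("reciprocal", "complement")) {
  simpson <- match.arg(simpson)
  m <- x$counts
  if (max(abs(m - round(m))) > 1e-9)
    stop("Chao1/ACE need integer counts; got non-integer abundances")
  m <- round(m)
  out <- data.frame(sample_id = rownames(m), stringsAsFactors = FALSE)
  idx <- t(apply(m, 1, function(v) {
    v <- v[v > 0]
    p <- v / sum(v)
    s_obs <- length(v)
    f1 <- sum(v == 1); f2 <- sum(v == 2)
    chao1 <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    rare <- v[v <= 10]
    if (length(rare) == 0) {
      ace <- s_obs
    } else {
      n_rare <- sum(rare)
      c_ace <- 1 - sum(rare == 1) / n_rare
      if (c_ace <= 0) {
        ace <- NA_real_  # all rare taxa are singletons: coverage undefined
      } else {
        s_rare <- length(rare)
        k <- 1:10
        fk <- vapply(k, function(j) sum(rare == j), numeric(1))
        g2 <- max(s_rare / c_ace * sum(k * (k - 1) * fk) /
                    (n_rare * (n_rare - 1)) - 1, 0)
        ace <- (s_obs - s_rare) + s_rare / c_ace +
          sum(rare == 1) / c_ace * g2
      }
    }
    simp_d <- sum(p^2)
    c(observed = s_obs,
      shannon = -sum(p * log(p, base = base)),
      simpson = if (simpson == "reciprocal") 1 / simp_d else 1 - simp_d,
      chao1 = chao1, ace = ace)
  }))
  cbind(out, as.data.frame(idx))
}

#' Two-group comparison of alpha indices
#'
#' Two-sided Wilcoxon rank-sum test (exact when sample sizes permit and there
#' are no ties) for each index column.
#'
#' @param alpha data.frame from [alpha_indices()] (or any numeric columns)
#' @param groups two-level factor aligned with the rows
#' @return named numeric vector of p-values
#' @export
compare_alpha <- function(alpha, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2)
    stop("exactly two groups required, found ", nlevels(groups))
  if (min(table(groups)) < 3) stop("each group needs n >= 3")
  num <- vapply(alpha, is.numeric, logical(1))
  vapply(alpha[num], function(v) rank_sum_p(v, groups), numeric(1))
}

## two-sided rank-sum p-value; exact when possible, midrank-normal otherwise
rank_sum_p <- function(v, groups) {
  g <- split(v, groups)
  if (anyNA(v)) return(NA_real_)
  if (length(unique(v)) == 1L) return(1)
  suppressWarnings(stats::wilcox.test(g[[1]], g[[2]])$p.value)
}

#' Pairwise beta-diversity distances
#'
#' Bray-Curtis (\eqn{\sum|x-y| / \sum(x+y)}, via vegan), unweighted UniFrac
#' (unshared branch length over the total branch length spanned by the union
#' of the two samples' taxa), or normalized weighted UniFrac
#' (\eqn{\sum_b l_b |p_{Ab}-p_{Bb}| / \sum_b l_b (p_{Ab}+p_{Bb})} over
#' branches b with descendant-proportions p).
#'
#' @param x an `abundance_table`
#' @param metric `"bray_curtis"`, `"unweighted_unifrac"` or
#'   `"weighted_unifrac"`
#' @param tree an `ape::phylo` whose tips cover the table's taxa (UniFrac
#'   only; extra tips are pruned)
#' @return a `dist` object with sample labels
#' @export
beta_distance <- function(x, metric = c("bray_curtis", "unweighted_unifrac",
                                        "weighted_unifrac"), tree = NULL) {
  metric <- match.arg(metric)
  if (metric == "bray_curtis")
    return(vegan::vegdist(x$counts, method = "bray"))
  if (is.null(tree)) stop("UniFrac metrics require a phylogenetic tree")
  missing <- setdiff(taxon_ids(x), tree$tip.label)
  if (length(missing))
    stop("taxa absent from the tree: ", paste(missing, collapse = ", "))
  extra <- setdiff(tree$tip.label, taxon_ids(x))
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  unifrac_dist(x$counts, tree, weighted = metric == "weighted_unifrac")
}

## UniFrac on a samples x taxa matrix and an ape tree.
## For each edge we need the set of tips below it; proportions/presence are
## aggregated per edge, then pairwise distances follow the branch formulas.
unifrac_dist <- function(m, tree, weighted = FALSE) {
  ntip <- length(tree$tip.label)
  m <- m[, tree$tip.label, drop = FALSE]
  len <- tree$edge.length
  if (is.null(len)) stop("tree has no branch lengths")
  ## tip-descendant incidence per edge, built by postorder accumulation
  nodes <- max(tree$edge)
  desc <- matrix(FALSE, nodes, ntip)
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(ord)))
    desc[ord[i, 1], ] <- desc[ord[i, 1], ] | desc[ord[i, 2], ]
  edge_desc <- desc[tree$edge[, 2], , drop = FALSE]  # edges x tips
  tot <- rowSums(m)
  P <- m / ifelse(tot > 0, tot, 1)           # sample x tip proportions
  EP <- P %*% t(edge_desc)                   # sample x edge proportions
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (weighted) {
      num <- sum(len * abs(EP[i, ] - EP[j, ]))
      den <- sum(len * (EP[i, ] + EP[j, ]))
    } else {
      a <- EP[i, ] > 0; b <- EP[j, ] > 0
      num <- sum(len[xor(a, b)])
      den <- sum(len[a | b])
    }
    D[i, j] <- D[j, i] <- if (den > 0) num / den else 0
  }
  stats::as.dist(D)
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers the squared distance matrix and eigendecomposes it.
#' Coordinates are returned for the positive eigenvalues only; all
#' eigenvalues (including negative ones, which flag non-Euclidean input)
#' are reported, with the proportion explained computed over the positive
#' part.
#'
#' @param d a `dist` or symmetric zero-diagonal matrix
#' @return list with `coordinates` (samples x axes), `eigenvalues`,
#'   `proportion_explained`
#' @export
pcoa <- function(d) {
  D <- as.matrix(d)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (max(abs(diag(D))) > 1e-8)
    stop("distance matrix must have a zero diagonal")
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-10 & e$values > 0
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = e$values,
       proportion_explained = if (any(pos))
         e$values[pos] / sum(e$values[pos]) else numeric(0))
}

#' PERMANOVA group-separation test
#'
#' One-way permutational multivariate analysis of variance on a distance
#' matrix.  The pseudo-F compares between- to within-group squared
#' distances; significance comes from label permutation:
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm).
#'
#' @param d `dist` or symmetric matrix
#' @param groups factor of group labels (>= 2 samples per group)
#' @param n_perm number of label permutations (>= 1)
#' @param seed optional seed for the permutations
#' @return list with `f_statistic`, `p_value`, `n_perm`
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  D2 <- as.matrix(d)^2
  groups <- droplevels(factor(groups))
  n <- nrow(D2)
  if (length(groups) != n) stop("groups length must match the matrix")
  if (min(table(groups)) < 2) stop("each group needs >= 2 samples")
  a <- nlevels(groups)
  sst <- sum(D2[upper.tri(D2)]) / n
  fstat <- function(g) {
    ssw <- 0
    for (lev in levels(groups)) {
      idx <- which(g == lev)
      ssw <- ssw + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
    }
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- fstat(groups)
  if (!is.finite(f_obs)) {
    warning("degenerate (constant) distance matrix; p = 1")
    return(list(f_statistic = NA_real_, p_value = 1, n_perm = n_perm))
  }
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm))
    if (fstat(sample(groups)) >= f_obs) hits <- hits + 1L
  list(f_statistic = f_obs, p_value = (1 + hits) / (1 + n_perm),
       n_perm = n_perm)
}

#' Full beta-diversity analysis for one metric
#'
#' Convenience wrapper: distance matrix, PCoA embedding, and (when groups are
#' given) a PERMANOVA group-separation test.
#'
#' @inheritParams beta_distance
#' @inheritParams permanova
#' @return list of class `beta_diversity` with `distance`, `metric`, `pcoa`,
#'   and optionally `permanova`
#' @export
beta_diversity <- function(x, metric = "bray_curtis", tree = NULL,
                           groups = NULL, n_perm = 999, seed = NULL) {
  d <- beta_distance(x, metric, tree)
  res <- list(distance = d, metric = metric, pcoa = pcoa(d))
  if (!is.null(groups))
    res$permanova <- permanova(d, groups, n_perm = n_perm, seed = seed)
  structure(res, class = "beta_diversity")
}

#' @export
print.beta_diversity <- function(x, ...) {
  cat("<beta_diversity>", x$metric, "on", attr(x$distance, "Size"),
      "samples\n")
  if (!is.null(x$permanova))
    cat(sprintf("  PERMANOVA F = %.3f, p = %.4g (%d permutations)\n",
                x$permanova$f_statistic, x$permanova$p_value,
                x$permanova$n_perm))
  invisible(x)
}
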