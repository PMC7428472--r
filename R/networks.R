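#' Distance correlation
#'
#' Szekely's distance correlation between two numeric vectors: pairwise
#' Euclidean distance matrices are double-centered, the distance covariance
#' is the mean of their elementwise product, and
#' dCor = dCov / sqrt(dVar_x dVar_y) (0 when either dVar is 0).  Lies in
#' [0, 1]; 0 in the population iff the variables are independent.
#'
#' @param x,y numeric vectors of equal length >= 4
#' @return dCor in [0, 1]
#' @export
distance_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("distance correlation needs n >= 4")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  A <- dcor_center(x)
  B <- dcor_center(y)
  dvx <- mean(A * A); dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(mean(A * B), 0) / sqrt(dvx * dvy))
}

## double-centered distance matrix of one vector
dcor_center <- function(x) {
  d <- abs(outer(x, x, `-`))
  d - outer(rowMeans(d), colMeans(d), `+`) + mean(d)
}

## t-approximation two-sided p for a Spearman rho (midranks under ties);
## exact permutation for very small n without ties via cor.test
spearman_test <- function(x, y) {
  n <- length(x)
  r <- stats::cor(rank(x), rank(y))
  if (is.na(r)) return(c(rho = NA_real_, p = NA_real_))
  if (n < 10 && !anyDuplicated(x) && !anyDuplicated(y)) {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    return(c(rho = unname(ct$estimate), p = ct$p.value))
  }
  if (abs(r) >= 1) return(c(rho = r, p = 0))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  c(rho = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

#' Spearman correlation edges
#'
#' All-pairs Spearman rank correlation within one (prevalence-filtered)
#' table; pairs with two-sided p < `alpha` become signed edges.
#'
#' @param x an `abundance_table` (relative abundances recommended)
#' @param alpha significance threshold (raw, uncorrected — matching the
#'   "only significant correlations (p < .05)" convention; see `adjust`)
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#' @return edge data.frame: `taxon_a`, `taxon_b`, `kingdom_a`, `kingdom_b`,
#'   `method`, `value`, `sign`, `p_value`
#' @export
spearman_edges <- function(x, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  m <- x$counts
  if (nrow(m) < 5) stop("need at least 5 samples")
  const <- apply(m, 2, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    warning("skipping constant taxa: ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  p <- ncol(m)
  if (p < 2) return(empty_edges())
  R <- apply(m, 2, rank)
  rho <- stats::cor(R)
  n <- nrow(m)
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[pairs]
  pv <- ifelse(abs(r) >= 1, 0,
               2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2))
  if (n < 10) {  # exact small-sample route, pair by pair
    for (k in seq_len(nrow(pairs))) {
      st <- spearman_test(m[, pairs[k, 1]], m[, pairs[k, 2]])
      r[k] <- st["rho"]; pv[k] <- st["p"]
    }
  }
  padj <- if (adjust == "BH") stats::p.adjust(pv, "BH") else pv
  keep <- !is.na(padj) & padj < alpha
  if (!any(keep)) return(empty_edges())
  data.frame(taxon_a = colnames(m)[pairs[keep, 1]],
             taxon_b = colnames(m)[pairs[keep, 2]],
             kingdom_a = x$kingdom, kingdom_b = x$kingdom,
             method = "spearman", value = r[keep],
             sign = ifelse(r[keep] >= 0, 1L, -1L),
             p_value = pv[keep], stringsAsFactors = FALSE)
}

empty_edges <- function() {
  data.frame(taxon_a = character(), taxon_b = character(),
             kingdom_a = character(), kingdom_b = character(),
             method = character(), value = numeric(), sign = integer(),
             p_value = numeric(), stringsAsFactors = FALSE)
}

#' Interkingdom distance-correlation edges
#'
#' For every cross-kingdom taxon pair the distance correlation is tested by
#' permutation: one margin is permuted `n_perm` times (the same permutation
#' set for every pair, drawn once from `seed`) and
#' p = (1 + #\{dCor_perm >= dCor_obs\}) / (1 + n_perm).  dCor is unsigned, so
#' each retained edge borrows its sign from the pair's Spearman rho.
#'
#' @param bact,fungi sample-aligned `abundance_table`s (prevalence-filtered
#'   upstream; relative abundances recommended)
#' @param alpha significance threshold on the permutation p
#' @param n_perm permutations (a warning is issued below 99)
#' @param seed RNG seed for the shared permutation set
#' @param adjust `"none"` or `"BH"`
#' @return edge data.frame as in [spearman_edges()], `method = "dcor"`
#' @export
dcor_edges <- function(bact, fungi, alpha = 0.05, n_perm = 999, seed = NULL,
                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!identical(sample_ids(bact), sample_ids(fungi)))
    stop("tables are not sample-aligned; run align_kingdoms() first")
  if (n_perm < 99)
    warning("n_perm < 99 gives a very coarse p-value resolution")
  n <- nrow(bact$counts)
  if (!is.null(seed)) set.seed(seed)
  perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
  A <- lapply(seq_len(ncol(bact$counts)),
              function(j) dcor_center(bact$counts[, j]))
  B <- lapply(seq_len(ncol(fungi$counts)),
              function(j) dcor_center(fungi$counts[, j]))
  dva <- vapply(A, function(a) mean(a * a), numeric(1))
  dvb <- vapply(B, function(b) mean(b * b), numeric(1))
  res <- list(); k <- 0L
  for (i in seq_along(A)) {
    if (dva[i] <= 0) next
    for (j in seq_along(B)) {
      if (dvb[j] <= 0) next
      denom <- sqrt(dva[i] * dvb[j])
      obs <- sqrt(max(mean(A[[i]] * B[[j]]), 0) / denom)
      hits <- 0L
      for (p_ in perms) {
        dc <- sqrt(max(mean(A[[i]] * B[[j]][p_, p_]), 0) / denom)
        if (dc >= obs) hits <- hits + 1L
      }
      k <- k + 1L
      res[[k]] <- c(i = i, j = j, value = obs,
                    p = (1 + hits) / (1 + n_perm))
    }
  }
  if (!k) return(empty_edges())
  res <- do.call(rbind, res)
  padj <- if (adjust == "BH") stats::p.adjust(res[, "p"], "BH") else
    res[, "p"]
  keep <- which(padj < alpha)
  if (!length(keep)) return(empty_edges())
  sgn <- vapply(keep, function(r) {
    rho <- stats::cor(rank(bact$counts[, res[r, "i"]]),
                      rank(fungi$counts[, res[r, "j"]]))
    if (!is.na(rho) && rho < 0) -1L else 1L
  }, integer(1))
  data.frame(taxon_a = taxon_ids(bact)[res[keep, "i"]],
             taxon_b = taxon_ids(fungi)[res[keep, "j"]],
             kingdom_a = bact$kingdom, kingdom_b = fungi$kingdom,
             method = "dcor", value = res[keep, "value"], sign = sgn,
             p_value = res[keep, "p"], stringsAsFactors = FALSE)
}

#' Assemble an association network
#'
#' Nodes are the taxa incident to at least one significant edge (so "number
#' of nodes" can shrink when structure is lost, as in the dysbiosis
#' comparison); degrees count incident edges.
#'
#' @param edges edge data.frame from [spearman_edges()] or [dcor_edges()]
#' @param group_label label of the sample group the network was built from
#' @param params list of build parameters (prevalence, alpha, n_perm, method)
#' @return object of class `association_network`
#' @export
association_network <- function(edges, group_label = "",
                                params = list()) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) && any(edges$taxon_a == edges$taxon_b))
    stop("self-edges are not allowed")
  key <- if (nrow(edges))
    paste(pmin(edges$taxon_a, edges$taxon_b),
          pmax(edges$taxon_a, edges$taxon_b)) else character()
  if (anyDuplicated(key)) stop("duplicate undirected edges")
  nodes <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
  degree <- if (length(nodes))
    table(factor(c(edges$taxon_a, edges$taxon_b), levels = nodes)) else
      table(factor(character()))
  kingdom <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  if (nrow(edges)) {
    kingdom[edges$taxon_a] <- edges$kingdom_a
    kingdom[edges$taxon_b] <- edges$kingdom_b
  }
  structure(list(edges = edges,
                 nodes = data.frame(taxon = nodes,
                                    kingdom = unname(kingdom[nodes]),
                                    degree = as.integer(degree),
                                    stringsAsFactors = FALSE),
                 group_label = group_label, params = params),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf("<association_network> %s: %d nodes, %d edges, connectedness %.3f\n",
              x$group_label, s$nodes, s$edges, s$connectedness))
  invisible(x)
}

#' Build a within-kingdom Spearman network for one group
#'
#' Applies the prevalence filter (strict >) to the group's samples, converts
#' to relative abundances, and keeps significant Spearman edges.
#'
#' @param x an `abundance_table` of counts (one kingdom)
#' @param group_label label stored on the network
#' @param prevalence prevalence threshold (default 0.5 — "> 50% of samples")
#' @param alpha edge significance threshold
#' @param adjust p-value adjustment passed to [spearman_edges()]
#' @return an `association_network`
#' @export
build_spearman_network <- function(x, group_label = "", prevalence = 0.5,
                                   alpha = 0.05, adjust = "none") {
  filt <- suppressWarnings(filter_prevalence(x, prevalence))
  edges <- if (ncol(filt$counts) >= 2)
    spearman_edges(relative_abundance(filt), alpha, adjust) else empty_edges()
  association_network(edges, group_label,
                      params = list(method = "spearman",
                                    prevalence = prevalence, alpha = alpha,
                                    n_perm = NA_integer_))
}

#' Build an interkingdom distance-correlation network for one group
#'
#' Both tables are prevalence-filtered (default 0.2 — "> 20% of samples"),
#' converted to relative abundances, and cross-kingdom pairs are tested by
#' permutation distance correlation.
#'
#' @inheritParams dcor_edges
#' @param group_label label stored on the network
#' @param prevalence prevalence threshold
#' @return an `association_network`
#' @export
build_interkingdom_network <- function(bact, fungi, group_label = "",
                                       prevalence = 0.2, alpha = 0.05,
                                       n_perm = 999, seed = NULL,
                                       adjust = "none") {
  fb <- suppressWarnings(filter_prevalence(bact, prevalence))
  ff <- suppressWarnings(filter_prevalence(fungi, prevalence))
  edges <- if (ncol(fb$counts) >= 1 && ncol(ff$counts) >= 1)
    dcor_edges(relative_abundance(fb), relative_abundance(ff), alpha,
               n_perm, seed, adjust) else empty_edges()
  association_network(edges, group_label,
                      params = list(method = "dcor", prevalence = prevalence,
                                    alpha = alpha, n_perm = n_perm))
}

#' Network summary statistics
#'
#' Relative connectedness is the field's density summary: significant edges
#' divided by nodes (taxa with at least one edge).
#'
#' @param net an `association_network`
#' @return list: `nodes`, `edges`, `connectedness`, `degree` (named vector),
#'   `mean_degree`, `sem_degree`
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "association_network"))
  n_nodes <- nrow(net$nodes)
  n_edges <- nrow(net$edges)
  if (n_nodes == 0) {
    warning("empty network")
    return(list(nodes = 0L, edges = 0L, connectedness = 0,
                degree = stats::setNames(numeric(0), character(0)),
                mean_degree = 0, sem_degree = NA_real_))
  }
  deg <- stats::setNames(net$nodes$degree, net$nodes$taxon)
  list(nodes = n_nodes, edges = n_edges,
       connectedness = n_edges / n_nodes, degree = deg,
       mean_degree = mean(deg),
       sem_degree = stats::sd(deg) / sqrt(length(deg)))
}

#' Compare two association networks
#'
#' Two-sided Mann-Whitney test on the node-degree distributions ("number of
#' neighbors"), plus both relative-connectedness values.  Both networks must
#' have been built with identical parameters.
#'
#' @param net1,net2 `association_network`s
#' @return data.frame with one row per network (`group`, `nodes`, `edges`,
#'   `connectedness`, `mean_degree`, `sem_degree`) carrying the degree-test
#'   p-value as attribute `p_value` and in column `degree_p`
#' @export
compare_networks <- function(net1, net2) {
  if (!identical(net1$params, net2$params))
    stop("networks were built with different parameters")
  s1 <- network_stats(net1); s2 <- network_stats(net2)
  if (s1$nodes < 2 || s2$nodes < 2)
    stop("both networks need at least 2 nodes to compare degrees")
  p <- suppressWarnings(
    stats::wilcox.test(s1$degree, s2$degree, exact = FALSE)$p.value)
  out <- data.frame(
    group = c(net1$group_label, net2$group_label),
    nodes = c(s1$nodes, s2$nodes), edges = c(s1$edges, s2$edges),
    connectedness = c(s1$connectedness, s2$connectedness),
    mean_degree = c(s1$mean_degree, s2$mean_degree),
    sem_degree = c(s1$sem_degree, s2$sem_degree),
    degree_p = p, stringsAsFactors = FALSE)
  attr(out, "p_value") <- p
  out
}

#' Write an edge list TSV
#'
#' @param net an `association_network`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a network to GraphML
#'
#' @param net an `association_network`
#' @param path output path (requires the igraph package)
#' @return `path`, invisibly
#' @export
write_graphml <- function(net, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("GraphML export requires the 'igraph' package")
  g <- igraph::graph_from_data_frame(
    net$edges[, c("taxon_a", "taxon_b", "method", "value", "sign",
                  "p_value")],
    directed = FALSE, vertices = net$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
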