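test_that("distance correlation has its defining extremes and symmetries", {
  set.seed(41)
  x <- rnorm(30)
  expect_equal(distance_correlation(x, 3 + 2 * x), 1, tolerance = 1e-10)
  expect_equal(distance_correlation(x, 1 - 0.5 * x), 1, tolerance = 1e-10)
  expect_equal(distance_correlation(x, rep(4, 30)), 0)
  y <- rnorm(30)
  expect_equal(distance_correlation(x, y), distance_correlation(y, x),
               tolerance = 1e-12)
  # invariance under shift and positive scaling of either argument
  expect_equal(distance_correlation(x, y),
               distance_correlation(5 + 3 * x, -2 + 0.1 * y),
               tolerance = 1e-10)
  expect_error(distance_correlation(x, y[1:10]), "equal length")
  expect_error(distance_correlation(1:3, 1:3), "n >= 4")
})

test_that("distance correlation matches the brute-force oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(8:20, 1)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    expect_equal(distance_correlation(x, y), dcor_brute(x, y),
                 tolerance = 1e-10)
  }
})

test_that("Spearman edges match rank-then-Pearson and the t-approximation", {
  set.seed(43)
  m <- matrix(rlnorm(40 * 6), 40, 6)
  m[, 2] <- exp(m[, 1])        # perfect monotone pair
  x <- make_at(m)
  e <- spearman_edges(x, alpha = 0.05)
  pair <- e[e$taxon_a == "T01" & e$taxon_b == "T02", ]
  expect_equal(pair$value, 1, tolerance = 1e-12)
  rel <- x$counts
  for (k in seq_len(nrow(e))) {
    a <- rel[, e$taxon_a[k]]; b <- rel[, e$taxon_b[k]]
    rho_oracle <- cor(rank(a), rank(b))        # rank-then-Pearson
    expect_equal(e$value[k], rho_oracle, tolerance = 1e-12)
    if (abs(rho_oracle) < 1) {
      ct <- suppressWarnings(cor.test(a, b, method = "spearman",
                                      exact = FALSE))
      expect_equal(e$p_value[k], ct$p.value, tolerance = 1e-9)
    }
  }
  expect_true(all(e$sign == sign(e$value)))
})

test_that("constant taxa are skipped with a warning", {
  set.seed(44)
  m <- cbind(matrix(rnorm(40, 10), 20, 2), rep(2, 20))
  colnames(m) <- c("T01", "T02", "T03")
  expect_warning(e <- spearman_edges(make_at(m)), "constant taxa: T03")
  expect_false("T03" %in% c(e$taxon_a, e$taxon_b))
})

test_that("edge discovery is monotone in alpha", {
  set.seed(45)
  x <- make_at(matrix(rlnorm(30 * 12), 30, 12))
  e1 <- spearman_edges(x, alpha = 0.01)
  e5 <- spearman_edges(x, alpha = 0.05)
  key <- function(e) paste(e$taxon_a, e$taxon_b)
  expect_true(all(key(e1) %in% key(e5)))
  expect_lte(nrow(e1), nrow(e5))
})

test_that("dcor edges recover a planted cross-kingdom pair and are seeded", {
  hits <- 0L
  for (s in 1:25) {
    set.seed(1000 + s)
    n <- 40
    z <- rnorm(n)  # latent factor; planted |r| = 0.7 on positive abundances
    bact <- make_at(cbind(sig = 10 + 0.7 * z + sqrt(1 - 0.49) * rnorm(n),
                          noiseb = 10 + rnorm(n)))
    fungi <- make_at(cbind(link = 10 + 0.7 * z + sqrt(1 - 0.49) * rnorm(n),
                           noisef = 10 + rnorm(n)), "fungi")
    e <- dcor_edges(bact, fungi, alpha = 0.05, n_perm = 199, seed = s)
    hits <- hits + ("sig" %in% e$taxon_a && "link" %in%
                      e$taxon_b[e$taxon_a == "sig"])
  }
  expect_gte(hits, 23)  # >= 90% power at |r| = 0.7, n = 40

  set.seed(46)
  b <- make_at(matrix(rlnorm(40 * 3), 40, 3))
  f <- make_at(matrix(rlnorm(40 * 3), 40, 3), "fungi")
  e1 <- dcor_edges(b, f, n_perm = 199, seed = 9)
  e2 <- dcor_edges(b, f, n_perm = 199, seed = 9)
  expect_identical(e1, e2)
  expect_warning(dcor_edges(b, f, n_perm = 50, seed = 1), "coarse")
})

test_that("network statistics follow the closed forms", {
  tri <- data.frame(taxon_a = c("a", "b", "c"), taxon_b = c("b", "c", "a"),
                    kingdom_a = "bacteria", kingdom_b = "bacteria",
                    method = "spearman", value = 0.9, sign = 1L,
                    p_value = 0.01)
  net <- association_network(tri, "g")
  s <- network_stats(net)
  expect_equal(s$connectedness, 1)
  expect_true(all(s$degree == 2))
  expect_equal(sum(s$degree), 2 * s$edges)

  k <- 6  # star with k leaves
  star <- data.frame(taxon_a = "hub", taxon_b = paste0("leaf", 1:k),
                     kingdom_a = "bacteria", kingdom_b = "fungi",
                     method = "dcor", value = 0.5, sign = 1L, p_value = 0.01)
  ss <- network_stats(association_network(star, "g"))
  expect_equal(unname(ss$degree["hub"]), k)
  expect_equal(ss$connectedness, k / (k + 1))

  expect_warning(s0 <- network_stats(association_network(tri[0, ], "g")),
                 "empty")
  expect_equal(s0$connectedness, 0)
  expect_error(association_network(
    data.frame(taxon_a = "a", taxon_b = "a", kingdom_a = "b",
               kingdom_b = "b", method = "spearman", value = 1, sign = 1L,
               p_value = 0.01)), "self-edges")
})

test_that("network comparison validates parameters and handles identity", {
  sim <- simulate_tables(network_contrast_scenario(seed = 2))
  idx <- split(seq_along(sim$meta$group), sim$meta$group)
  ctrl <- suppressWarnings(build_spearman_network(
    group_subset(sim$bact, idx$control), "control"))
  case <- suppressWarnings(build_spearman_network(
    group_subset(sim$bact, idx$case), "case"))
  cmp <- compare_networks(ctrl, case)
  expect_equal(cmp$connectedness * cmp$nodes, cmp$edges, tolerance = 1e-12)
  expect_gt(cmp$connectedness[1], cmp$connectedness[2])
  expect_lt(cmp$degree_p[1], 1e-4)

  same <- compare_networks(ctrl, ctrl)
  expect_gt(same$degree_p[1], 0.9)

  other <- suppressWarnings(build_spearman_network(
    group_subset(sim$bact, idx$case), "case", alpha = 0.01))
  expect_error(compare_networks(ctrl, other), "different parameters")
  tiny <- association_network(mycobnet:::empty_edges(), "x",
                              params = ctrl$params)
  expect_error(suppressWarnings(compare_networks(ctrl, tiny)),
               "at least 2 nodes")
})

test_that("edge lists and GraphML exports are written", {
  sim <- simulate_tables(network_contrast_scenario(seed = 3))
  idx <- split(seq_along(sim$meta$group), sim$meta$group)
  net <- suppressWarnings(build_spearman_network(
    group_subset(sim$bact, idx$control), "control"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, tsv)
  re <- read.delim(tsv)
  expect_identical(nrow(re), nrow(net$edges))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_equal(igraph::vcount(g), nrow(net$nodes))
})
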