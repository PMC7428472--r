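test_that("alpha indices match hand-computed values on toy vectors", {
  x <- make_at(rbind(c(5, 5, 5, 5)))
  a <- alpha_indices(x)
  expect_equal(a$shannon, log(4), tolerance = 1e-12)
  expect_equal(a$simpson, 4, tolerance = 1e-12)
  expect_equal(a$observed, 4)

  # S_obs = 5, F1 = 2, F2 = 1 -> bias-corrected Chao1 = 5 + 2*1/(2*2) = 5.5
  y <- make_at(rbind(c(4, 3, 2, 1, 1)))
  expect_equal(alpha_indices(y)$chao1, 5.5, tolerance = 1e-12)

  # no rare taxa (all counts > 10) -> ACE equals observed richness
  z <- make_at(rbind(c(20, 30, 40)))
  expect_equal(alpha_indices(z)$ace, 3)

  # single-taxon sample: Shannon 0, reciprocal Simpson 1
  s <- alpha_indices(make_at(rbind(c(17))))
  expect_equal(s$shannon, 0)
  expect_equal(s$simpson, 1)

  expect_error(alpha_indices(make_at(rbind(c(1.5, 2)))), "integer counts")
})

test_that("alpha indices agree with the vegan oracles on random tables", {
  set.seed(21)
  m <- matrix(rnbinom(400, mu = 8, size = 0.7), 10, 40)
  m[1, ] <- m[1, ] + 1  # avoid empty sample
  x <- make_at(m)
  a <- alpha_indices(x)
  expect_equal(a$shannon, unname(vegan::diversity(m, "shannon")),
               tolerance = 1e-10)
  expect_equal(a$simpson, unname(vegan::diversity(m, "invsimpson")),
               tolerance = 1e-10)
  est <- vegan::estimateR(m)
  expect_equal(a$chao1, unname(est["S.chao1", ]), tolerance = 1e-8)
  expect_equal(a$ace, unname(est["S.ACE", ]), tolerance = 1e-8)
})

test_that("adding an all-zero taxon changes no alpha index", {
  set.seed(22)
  m <- matrix(rpois(50, 6), 5, 10)
  m2 <- cbind(m, 0)
  colnames(m2) <- sprintf("T%02d", 1:11)
  expect_equal(alpha_indices(make_at(m))[, -1],
               alpha_indices(make_at(m2))[, -1])
})

test_that("Bray-Curtis matches the count-based formula", {
  x <- make_at(rbind(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(as.numeric(beta_distance(x, "bray_curtis")), 4 / 12)
  # disjoint support -> 1; identity -> 0
  d <- make_at(rbind(c(5, 0), c(0, 7)))
  expect_equal(as.numeric(beta_distance(d, "bray_curtis")), 1)
  set.seed(23)
  m <- matrix(rpois(60, 5), 6, 10)
  D <- as.matrix(beta_distance(make_at(m), "bray_curtis"))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(D[i, j], sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ]),
                 tolerance = 1e-12)
})

test_that("UniFrac matches hand computations on toy trees", {
  two <- ape::read.tree(text = "(A:1,B:1);")
  x <- make_at(rbind(S1 = c(A = 3, B = 0), S2 = c(A = 0, B = 5)))
  expect_equal(as.numeric(beta_distance(x, "unweighted_unifrac", two)), 1)
  expect_equal(as.numeric(beta_distance(x, "weighted_unifrac", two)), 1)

  # ((A,B),(C,D)) with unit branches; S1 = {A,C}, S2 = {A,D}:
  # unique branch length 2 (tips C and D) over union length 5 -> 0.4;
  # weighted: sum l|dp| = 1 over sum l(p1+p2) = 4 -> 0.25
  four <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  y <- make_at(rbind(S1 = c(A = 1, B = 0, C = 1, D = 0),
                     S2 = c(A = 1, B = 0, C = 0, D = 1)))
  expect_equal(as.numeric(beta_distance(y, "unweighted_unifrac", four)), 0.4)
  expect_equal(as.numeric(beta_distance(y, "weighted_unifrac", four)), 0.25)

  # identical samples -> 0 for both metrics
  z <- make_at(rbind(S1 = c(A = 2, B = 1, C = 0, D = 1),
                     S2 = c(A = 2, B = 1, C = 0, D = 1)))
  expect_equal(as.numeric(beta_distance(z, "unweighted_unifrac", four)), 0)
  expect_equal(as.numeric(beta_distance(z, "weighted_unifrac", four)), 0)

  # disjoint samples on a star tree -> 1
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  w <- make_at(rbind(S1 = c(A = 1, B = 1, C = 0, D = 0),
                     S2 = c(A = 0, B = 0, C = 3, D = 2)))
  expect_equal(as.numeric(beta_distance(w, "unweighted_unifrac", star)), 1)

  expect_error(beta_distance(x, "unweighted_unifrac"), "require a .*tree")
  missing_tree <- ape::read.tree(text = "(A:1,X:1);")
  expect_error(beta_distance(x, "unweighted_unifrac", missing_tree),
               "absent from the tree: B")
})

test_that("UniFrac agrees with the phyloseq oracle on random data", {
  set.seed(24)
  ntip <- 12
  tree <- ape::rtree(ntip, tip.label = sprintf("T%02d", 1:ntip))
  m <- matrix(rpois(8 * ntip, 4), 8, ntip,
              dimnames = list(sprintf("S%02d", 1:8), tree$tip.label))
  m[1, ] <- m[1, ] + 1
  x <- make_at(m)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(t(m), taxa_are_rows = TRUE),
    phyloseq::phy_tree(tree))
  expect_equal(as.matrix(beta_distance(x, "unweighted_unifrac", tree)),
               as.matrix(phyloseq::UniFrac(ps, weighted = FALSE)),
               tolerance = 1e-8)
  expect_equal(as.matrix(beta_distance(x, "weighted_unifrac", tree)),
               as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                           normalized = TRUE)),
               tolerance = 1e-8)
})

test_that("PCoA recovers known geometry", {
  # equilateral triangle, side 1: two equal positive eigenvalues, third ~ 0
  D <- matrix(1, 3, 3) - diag(3)
  dimnames(D) <- list(letters[1:3], letters[1:3])
  p <- pcoa(D)
  expect_equal(p$eigenvalues[1], p$eigenvalues[2], tolerance = 1e-10)
  expect_equal(p$eigenvalues[1], 0.5, tolerance = 1e-10)
  expect_lt(abs(p$eigenvalues[3]), 1e-10)

  # Euclidean distances of known 2-D points reconstruct within 1e-8
  set.seed(25)
  pts <- matrix(rnorm(20), 10, 2)
  D2 <- as.matrix(dist(pts))
  emb <- pcoa(D2)
  expect_true(all(emb$eigenvalues > -1e-10))
  rec <- as.matrix(dist(emb$coordinates[, 1:2]))
  expect_equal(unname(rec), unname(D2), tolerance = 1e-8)

  # duplicated point -> identical embedding rows
  D3 <- as.matrix(dist(pts[c(1, 1, 2:6), ]))
  e3 <- pcoa(D3)
  expect_equal(e3$coordinates[1, ], e3$coordinates[2, ], tolerance = 1e-8)

  bad <- D2; bad[1, 2] <- bad[1, 2] + 1
  expect_error(pcoa(bad), "symmetric")
})

test_that("permanova separates planted clusters and matches vegan's F", {
  set.seed(26)
  pts <- rbind(matrix(rnorm(40), 10, 4),
               matrix(rnorm(40, mean = 3), 10, 4))
  D <- dist(pts)
  g <- factor(rep(c("a", "b"), each = 10))
  res <- permanova(D, g, n_perm = 999, seed = 1)
  expect_lte(res$p_value, 0.01)
  ad <- vegan::adonis2(D ~ g, permutations = 99)
  expect_equal(res$f_statistic, ad$F[1], tolerance = 1e-8)
  expect_error(permanova(D, g, n_perm = 0), "n_perm")
  expect_warning(p1 <- permanova(as.dist(matrix(0, 6, 6)),
                                 factor(rep(1:2, 3)), n_perm = 19),
                 "degenerate")
  expect_equal(p1$p_value, 1)
})

test_that("compare_alpha reproduces the exact rank-sum tail and validates", {
  v <- c(11:20, 1:10)  # group1 strictly above group2, n = 10/10
  g <- factor(rep(c("g1", "g2"), each = 10))
  p <- compare_alpha(data.frame(idx = v), g)
  expect_equal(unname(p["idx"]), 2 / choose(20, 10), tolerance = 1e-12)
  expect_error(compare_alpha(data.frame(idx = v), factor(rep("g1", 20))),
               "two groups")
  tied <- compare_alpha(data.frame(idx = rep(1, 20)), g)
  expect_equal(unname(tied["idx"]), 1)
})

test_that("planted lower fungal richness is detected by Chao1/ACE", {
  # cases lose a band of mid-tail fungal taxa (strong depletion): the
  # richness estimators should find the direction nearly always
  hits <- 0L
  for (s in 1:15) {
    lost <- sprintf("Fungi_g%03d", 20:39)  # mid/low-tail taxa, wiped in cases
    sc <- scenario_config(
      n_group1 = 12, n_group2 = 12, n_bact_taxa = 10, n_fungi_taxa = 40,
      base_log_abundance = c(rep(0, 10), seq(2, -2, length.out = 40)),
      depth_range = c(3000L, 6000L),
      diff_taxa = data.frame(taxon = lost, kingdom = "fungi", log2fc = -8,
                             group = "group1"),
      seed = 100 + s)
    sim <- simulate_tables(sc)
    a <- alpha_indices(sim$fungi)
    grp <- sim$meta$group
    dir_ok <- mean(a$chao1[grp == "group1"]) < mean(a$chao1[grp == "group2"])
    p <- compare_alpha(a[c("chao1", "ace")], grp)
    hits <- hits + (dir_ok && p["chao1"] < 0.05)
  }
  expect_gte(hits, 14)
})
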