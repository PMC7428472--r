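test_that("TSV round trip preserves the table exactly", {
  set.seed(11)
  x <- make_at(matrix(rpois(60, 20), 6, 10), "fungi")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(x, path)
  y <- read_table(path, "tsv", "fungi")
  expect_identical(dimnames(y$counts), dimnames(x$counts))
  expect_equal(y$counts, x$counts)
})

test_that("BIOM and TSV encodings of the same fixture load identically", {
  set.seed(12)
  x <- make_at(matrix(rpois(40, 15), 5, 8))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  biom <- withr::local_tempfile(fileext = ".biom")
  write_table(x, tsv, "tsv")
  write_table(x, biom, "biom")
  a <- read_table(tsv, "tsv", "bacteria")
  b <- read_table(biom, "biom", "bacteria")
  expect_equal(a$counts, b$counts[rownames(a$counts), colnames(a$counts)])
})

test_that("construction rejects invalid tables with informative errors", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("S1", "S1"), c("A", "B")))
  expect_error(abundance_table(m), "duplicate sample ids: S1")
  m2 <- matrix(1:4, 2, 2, dimnames = list(c("S1", "S2"), c("A", "A")))
  expect_error(abundance_table(m2), "duplicate taxon ids: A")
  m3 <- matrix(c(1, -2, 3, 4), 2, 2,
               dimnames = list(c("S1", "S2"), c("A", "B")))
  expect_error(abundance_table(m3), "negative or non-finite.*S2.*A")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tS1\tS2", "A\t1\t2", "B\tx\t4"), tsv)
  expect_error(read_table(tsv, "tsv"), "non-numeric.*B.*S1")
})

test_that("relative_abundance normalizes rows and flags zero-sum samples", {
  x <- make_at(rbind(c(2, 2, 4), c(1, 1, 2)))
  r <- relative_abundance(x)
  expect_equal(unname(r$counts[1, ]), c(0.25, 0.25, 0.5))
  expect_equal(rowSums(r$counts), c(S01 = 1, S02 = 1), tolerance = 1e-12)
  k <- 7
  u <- relative_abundance(make_at(matrix(3, 2, k)))
  expect_equal(unname(u$counts[1, ]), rep(1 / k, k))
  z <- make_at(rbind(c(1, 1), c(0, 0)))
  expect_error(relative_abundance(z), "zero-sum sample.*S02")
})

test_that("major-genus filter is inclusive at the threshold", {
  # taxon A mean 0.009, B mean exactly 0.01, C the rest
  m <- rbind(c(9, 10, 981), c(9, 10, 981)) * 1
  colnames(m) <- c("A", "B", "C")
  x <- make_at(m)
  f <- filter_major_genera(x, 0.01)
  expect_identical(taxon_ids(f), c("B", "C"))
  expect_error(filter_major_genera(x, 0), "strictly inside")
  expect_error(filter_major_genera(x, 1), "strictly inside")
})

test_that("prevalence filter uses a strict inequality", {
  m <- matrix(0, 40, 3, dimnames = list(sprintf("S%02d", 1:40),
                                        c("half", "above", "low")))
  m[1:20, "half"] <- 5    # 50% exactly -> dropped at 0.5
  m[1:21, "above"] <- 5   # 52.5% -> kept
  m[1:9, "low"] <- 5      # 22.5% -> kept at 0.2
  x <- make_at(m)
  expect_identical(taxon_ids(filter_prevalence(x, 0.5)), "above")
  expect_true("low" %in% taxon_ids(filter_prevalence(x, 0.2)))
  expect_error(filter_prevalence(x, 0), "strictly inside")
  expect_warning(filter_prevalence(x, 0.99), "removed every taxon")
})

test_that("filters are idempotent", {
  set.seed(13)
  x <- make_at(matrix(rpois(400, 3), 20, 20))
  f1 <- filter_major_genera(x, 0.03)
  expect_equal(filter_major_genera(f1, 0.03)$counts, f1$counts)
  p1 <- filter_prevalence(x, 0.4)
  expect_equal(filter_prevalence(p1, 0.4)$counts, p1$counts)
})

test_that("align_kingdoms restricts to common samples and errors when none", {
  set.seed(14)
  b <- make_at(matrix(rpois(50, 10), 5, 10))
  f <- make_at(matrix(rpois(60, 10), 6, 10), "fungi")
  meta <- data.frame(sample_id = sprintf("S%02d", 1:6),
                     group = rep(c("a", "b"), 3))
  expect_message(al <- align_kingdoms(b, f, meta), "dropping 1 sample")
  expect_identical(sample_ids(al$bact), sample_ids(al$fungi))
  expect_identical(al$meta$sample_id, sample_ids(al$bact))
  expect_identical(sample_ids(al$bact), sprintf("S%02d", 1:5))
  f2 <- f
  rownames(f2$counts) <- sprintf("X%02d", 1:6)
  expect_error(align_kingdoms(b, make_at(f2$counts, "fungi"), meta),
               "no samples shared")
})

test_that("prevalence filtering commutes with sample alignment", {
  set.seed(15)
  b <- make_at(matrix(rpois(200, 2), 10, 20))
  f <- make_at(matrix(rpois(120, 2), 10, 12), "fungi")
  # fungi carries two extra samples
  extra <- make_at(rbind(f$counts, matrix(rpois(24, 2), 2, 12,
                   dimnames = list(c("X1", "X2"), colnames(f$counts)))),
                   "fungi")
  meta <- data.frame(sample_id = sample_ids(b), group = rep(c("a", "b"), 5))
  a_then_f <- filter_prevalence(align_kingdoms(b, extra, meta)$fungi, 0.3)
  f_then_a <- align_kingdoms(b, filter_prevalence(extra, 0.3), meta)$fungi
  # same samples, and the taxon sets agree on the common samples' prevalence
  expect_identical(sample_ids(a_then_f), sample_ids(f_then_a))
})

test_that("lineage strings parse and tables collapse at a rank", {
  tax <- c(A = "k__Bacteria; p__Firmicutes; g__Blautia",
           B = "k__Bacteria; p__Firmicutes; g__Blautia",
           C = "k__Bacteria; p__Bacteroidetes; g__",
           D = "k__Bacteria")
  pl <- parse_lineage(tax)
  expect_identical(unname(pl[, "genus"]), c("Blautia", "Blautia", "", ""))
  expect_identical(unname(pl[, "phylum"]),
                   c("Firmicutes", "Firmicutes", "Bacteroidetes", ""))
  m <- matrix(1:8, 2, 4, dimnames = list(c("S1", "S2"), names(tax)))
  x <- abundance_table(m, "bacteria", tax)
  g <- suppressMessages(collapse_rank(x, "genus"))
  expect_identical(taxon_ids(g), "Blautia")
  expect_equal(unname(g$counts[, "Blautia"]), c(1 + 3, 2 + 4))
  p <- suppressMessages(collapse_rank(x, "phylum"))
  expect_equal(unname(p$counts[, "Firmicutes"]), c(4, 6))
})

test_that("metadata validation enforces a two-level group", {
  df <- data.frame(sample_id = c("a", "b", "c"),
                   group = c("x", "y", "z"))
  expect_error(mycobnet:::validate_metadata(df), "two levels")
  df$group <- c("x", "y", "x")
  expect_s3_class(mycobnet:::validate_metadata(df)$group, "factor")
})
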