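test_that("count tables round-trip through TSV", {
  tab <- toy_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, path)
  back <- read_count_table(path, metadata = tab$metadata)
  expect_identical(back$counts, tab$counts)
  expect_equal(dim(back), c(3, 2))
  # write(read(f)) == read(f)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed count tables are rejected with the offending id", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts1", "t1\t1\t2", "t2\t3\t4"), path)
  expect_error(read_count_table(path), "s1", class = "soilnet_format_error")

  writeLines(c("taxon_id\ts1\ts2", "t1\t1\t2", "t1\t3\t4"), path)
  expect_error(read_count_table(path), "t1", class = "soilnet_format_error")

  writeLines(c("taxon_id\ts1\ts2", "t1\t1\tx", "t2\t3\t4"), path)
  expect_error(read_count_table(path), "s2", class = "soilnet_format_error")

  m <- matrix(c(-1, 2, 3, 4), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(asv_table(m, data.frame(sample_id = c("s1", "s2"), group = "g")),
               class = "soilnet_format_error")
  m2 <- matrix(c(0.5, 2, 3, 4), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(asv_table(m2, data.frame(sample_id = c("s1", "s2"), group = "g")),
               "non-integer", class = "soilnet_format_error")
})

test_that("rarefaction subsamples to exact depth without replacement", {
  m <- matrix(c(10L, 0L, 5L,
                40L, 30L, 30L), ncol = 2,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  tab <- asv_table(m, data.frame(sample_id = c("s1", "s2"), group = "g"))

  r <- rarefy_counts(tab, depth = 15, seed = 1)
  expect_identical(r$counts[, "s1"], m[, "s1"])   # already at depth
  expect_equal(unname(colSums(r$counts)), c(15, 15))
  expect_true(all(r$counts <= m))

  # default depth = minimum column sum
  r2 <- rarefy_counts(tab, seed = 1)
  expect_equal(unname(colSums(r2$counts)), c(15, 15))

  # single-taxon sample: forced outcome
  m3 <- matrix(100L, 1, 1, dimnames = list("t1", "s1"))
  tab3 <- asv_table(m3, data.frame(sample_id = "s1", group = "g"))
  expect_equal(unname(rarefy_counts(tab3, depth = 40, seed = 2)$counts[1, 1]), 40)

  # determinism and error contract
  expect_identical(rarefy_counts(tab, depth = 12, seed = 9)$counts,
                   rarefy_counts(tab, depth = 12, seed = 9)$counts)
  expect_error(rarefy_counts(tab, depth = 50), "s1",
               class = "soilnet_invalid_argument")
})

test_that("rarefaction is unbiased in expectation", {
  m <- matrix(c(60L, 30L, 10L), ncol = 1, dimnames = list(c("a", "b", "c"), "s"))
  tab <- asv_table(m, data.frame(sample_id = "s", group = "g"))
  acc <- matrix(0, 3, 1000)
  for (r in seq_len(1000)) {
    acc[, r] <- rarefy_counts(tab, depth = 40, seed = r)$counts[, 1]
  }
  expected <- m[, 1] * 40 / 100
  expect_true(all(abs(rowMeans(acc) - expected) / expected < 0.05))
})

test_that("prevalence filter applies the at-least-half rule with ceiling", {
  n <- 16
  m <- rbind(
    kept = c(rep(1L, 8), rep(0L, 8)),     # 8 of 16 = ceiling(0.5*16)
    dropped = c(rep(1L, 7), rep(0L, 9)),  # 7 of 16 < 8
    everywhere = rep(2L, n))
  colnames(m) <- sprintf("s%02d", 1:n)
  tab <- asv_table(m, data.frame(sample_id = colnames(m), group = "down"))

  f <- filter_prevalence(tab, "down", 0.5)
  expect_setequal(rownames(f$counts), c("kept", "everywhere"))

  # min_fraction 1 drops any taxon with an absence
  f1 <- filter_prevalence(tab, "down", 1)
  expect_identical(rownames(f1$counts), "everywhere")

  # idempotence
  expect_identical(filter_prevalence(f, "down", 0.5)$counts, f$counts)

  expect_error(filter_prevalence(tab, "nope"), "nope",
               class = "soilnet_invalid_argument")
})

test_that("taxon aggregation conserves totals", {
  m <- matrix(c(3L, 4L, 2L,
                1L, 5L, 7L), ncol = 2,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  tab <- asv_table(m, data.frame(sample_id = c("s1", "s2"), group = "g"))
  taxonomy <- data.frame(taxon_id = c("t1", "t2"),
                         phylum = c("P1", "P1"))
  agg <- aggregate_taxa(tab, taxonomy)
  expect_equal(unname(agg$counts["P1", ]), unname(m["t1", ] + m["t2", ]))
  expect_equal(unname(agg$counts["unclassified", ]), unname(m["t3", ]))
  expect_equal(colSums(agg$counts), colSums(m))

  identity_map <- data.frame(taxon_id = rownames(m), phylum = rownames(m))
  agg_id <- aggregate_taxa(tab, identity_map)
  expect_identical(agg_id$counts[rownames(m), ], m)
})

test_that("relative abundance normalizes columns to one", {
  m <- matrix(c(2L, 2L, 1L, 1L, 1L, 1L), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  tab <- asv_table(m, data.frame(sample_id = c("s1", "s2"), group = "g"))
  rel <- relative_abundance(tab)
  expect_equal(unname(colSums(rel)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(rel[, "s1"]), c(0.4, 0.4, 0.2))
  expect_true(all(rel >= 0 & rel <= 1))

  m0 <- matrix(c(0L, 0L, 1L, 1L), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  tab0 <- asv_table(m0, data.frame(sample_id = c("s1", "s2"), group = "g"))
  expect_error(relative_abundance(tab0), "s1",
               class = "soilnet_invalid_argument")
})
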