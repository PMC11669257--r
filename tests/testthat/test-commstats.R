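test_that("alpha diversity matches hand-evaluated richness and Shannon", {
  m <- matrix(c(5L, 5L, 5L, 5L,
                10L, 0L, 0L, 0L,
                1L, 1L, 2L, 0L), ncol = 3,
              dimnames = list(c("a", "b", "c", "d"), c("s1", "s2", "s3")))
  tab <- asv_table(m, data.frame(sample_id = c("s1", "s2", "s3"), group = "g"))
  a <- alpha_diversity(tab)
  expect_equal(a$richness, c(4L, 1L, 3L))
  expect_equal(a$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(a$shannon[2], 0, tolerance = 1e-12)
  expect_equal(a$shannon[3],
               -(0.25 * log(0.25) + 0.25 * log(0.25) + 0.5 * log(0.5)),
               tolerance = 1e-12)

  m0 <- matrix(c(0L, 0L, 1L, 1L), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  tab0 <- asv_table(m0, data.frame(sample_id = c("s1", "s2"), group = "g"))
  expect_error(alpha_diversity(tab0), class = "soilnet_invalid_argument")
})

test_that("weighted UniFrac matches the branch-weighted formula", {
  tree <- two_tip_tree(1)
  m <- matrix(c(10L, 0L, 0L, 10L), 2,
              dimnames = list(c("t1", "t2"), c("A", "B")))
  tab <- asv_table(m, data.frame(sample_id = c("A", "B"), group = "g"))
  expect_equal(as.numeric(weighted_unifrac(tab, tree, normalized = FALSE)), 2)
  expect_equal(as.numeric(weighted_unifrac(tab, tree, normalized = TRUE)), 1)

  # identical samples at distance zero; symmetry and zero diagonal
  sim <- simulate_dataset(synth_config(n_taxa = 30, group_sizes = c(a = 4),
                                       n_blocks = 1, block_size = 5,
                                       depth_range = c(500, 800), seed = 3))
  m2 <- sim$table$counts
  m2 <- cbind(m2, dup = m2[, 1])
  tab2 <- asv_table(m2, data.frame(sample_id = colnames(m2), group = "g"))
  d <- as.matrix(weighted_unifrac(tab2, sim$tree))
  expect_equal(unname(d[1, "dup"]), 0, tolerance = 1e-12)
  expect_equal(d, t(d), tolerance = 1e-12)
  expect_true(all(diag(d) == 0))

  bad <- asv_table(matrix(1L, 1, 2, dimnames = list("nope", c("A", "B"))),
                   data.frame(sample_id = c("A", "B"), group = "g"))
  expect_error(weighted_unifrac(bad, tree), "nope",
               class = "soilnet_invalid_argument")
})

test_that("PCoA reproduces simple geometries", {
  # equilateral triangle: two equal positive eigenvalues, third ~ 0
  d <- matrix(1, 3, 3) - diag(3)
  dimnames(d) <- list(paste0("s", 1:3), paste0("s", 1:3))
  ord <- pcoa_ordination(d)
  eig <- ord$eigenvalues
  expect_equal(eig[1], eig[2], tolerance = 1e-10)
  expect_lt(abs(eig[3]), 1e-10)
  expect_lte(sum(ord$prop_explained), 1 + 1e-12)

  # reconstructed distances match the input for a Euclidean configuration
  co <- as.matrix(ord$coordinates[, c("Axis.1", "Axis.2")])
  expect_equal(unname(as.matrix(dist(co))), unname(d), tolerance = 1e-8)

  # degenerate all-zero distances give all-zero coordinates
  z <- matrix(0, 3, 3, dimnames = dimnames(d))
  ordz <- pcoa_ordination(z)
  expect_true(all(abs(as.matrix(ordz$coordinates[, -1])) < 1e-12))

  d_bad <- d; d_bad[1, 2] <- 5
  expect_error(pcoa_ordination(d_bad), class = "soilnet_invalid_argument")
})

test_that("PERMANOVA detects perfect separation and is reproducible", {
  # two tight clusters: within distance 0, between 1
  d <- matrix(1, 6, 6); d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0; diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  grp <- setNames(rep(c("x", "y"), each = 3), rownames(d))
  res <- permanova(d, grp, n_permutations = 199, seed = 1)
  expect_equal(res$p_value, 1 / 200, tolerance = 1e-12)
  expect_gte(res$R2, 0); expect_lte(res$R2, 1 + 1e-12)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)

  res2 <- permanova(d, grp, n_permutations = 199, seed = 1)
  expect_equal(glance(res), glance(res2), tolerance = 1e-15)

  expect_error(permanova(d, setNames(c("x", rep("y", 5)), rownames(d))),
               class = "soilnet_invalid_argument")
  expect_identical(tidy(res)$pseudo_F, res$pseudo_F)
})

test_that("per-feature Wilcoxon with BH matches the step-up oracle", {
  set.seed(42)
  m <- matrix(rnorm(20 * 12), 20,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:12)))
  m[1, 1:6] <- m[1, 1:6] + 5          # one real difference
  m[20, ] <- 3                        # constant feature
  grp <- setNames(rep(c("a", "b"), each = 6), colnames(m))
  res <- wilcoxon_bh(m, grp, "a", "b")
  expect_equal(res$p_adjusted, bh_oracle(res$p_value), tolerance = 1e-12)
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(res$constant[res$feature == "f20"])
  expect_equal(res$p_value[res$feature == "f20"], 1)
  expect_lt(res$p_adjusted[res$feature == "f1"], 0.05)

  # identical groups: all p = 1
  m2 <- cbind(m[1:5, 1:4], m[1:5, 1:4])
  colnames(m2) <- paste0("s", 1:8)
  res2 <- wilcoxon_bh(m2, setNames(rep(c("a", "b"), each = 4), colnames(m2)),
                      "a", "b")
  expect_true(all(res2$p_value == 1))

  # hand BH example: (0.01, 0.02, 0.03, 0.04) all adjust to 0.04
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
})

test_that("one-way ANOVA with Tukey letters matches the hand partition", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  res <- anova_tukey(vals, grp)
  expect_equal(res$F_value, 27, tolerance = 1e-12)   # SSB=54, SSW=6, df 2/6
  expect_equal(res$df, c(2, 6))
  # all pairwise Tukey significant except g1-g2? check letters contract:
  # groups with no non-significant partner get distinct letters
  sig <- res$tukey$p_adjusted < 0.05
  if (all(sig)) expect_equal(length(unique(res$letters$letters)), 3)

  # two identical groups: F ~ 0, Tukey p ~ 1, shared letter
  res2 <- anova_tukey(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_lt(res2$F_value, 1e-10)
  expect_gt(res2$tukey$p_adjusted[1], 0.99)
  expect_equal(res2$letters$letters[1], res2$letters$letters[2])

  # log10 path records the zero offset
  res3 <- anova_tukey(c(0, 1, 2, 10, 20, 30), rep(c("a", "b"), each = 3),
                      log10_transform = TRUE)
  expect_equal(res3$zero_offset, 0.5)

  expect_error(anova_tukey(c(1, 1, 2, 2), rep(c("a", "b"), each = 2)),
               class = "soilnet_invalid_argument")
})
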