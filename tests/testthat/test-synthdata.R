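test_that("simulated trees are rooted, bifurcating and reproducible", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_equal(t2$Nnode, 1)

  t100 <- simulate_tree(100, seed = 7)
  expect_equal(ape::Ntip(t100), 100)
  expect_equal(t100$Nnode, 99)          # 2n - 1 nodes for a binary tree
  expect_true(ape::is.binary(t100))
  expect_true(ape::is.rooted(t100))
  expect_true(all(t100$edge.length > 0))
  expect_equal(anyDuplicated(t100$tip.label), 0)

  expect_identical(ape::write.tree(simulate_tree(50, seed = 3)),
                   ape::write.tree(simulate_tree(50, seed = 3)))
  expect_error(simulate_tree(1), class = "soilnet_invalid_argument")
})

test_that("Brownian traits respect the branch-length variance law", {
  # zero-length cherry: tips with zero patristic distance share the trait
  tree <- ape::read.tree(text = "((a:0,b:0):1,c:2);")
  tr <- simulate_trait(tree, seed = 1)
  expect_identical(tr[["a"]], tr[["b"]])

  # expected squared difference grows with patristic distance: regress
  # mean squared trait contrasts on distance over replicates, slope > 0
  tree2 <- simulate_tree(12, seed = 5)
  D <- ape::cophenetic.phylo(tree2)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  sq <- matrix(0, nrow(pairs), 200)
  for (r in seq_len(200)) {
    z <- simulate_trait(tree2, seed = 1000 + r)
    sq[, r] <- (z[rownames(D)[pairs[, 1]]] - z[rownames(D)[pairs[, 2]]])^2
  }
  fit <- lm(rowMeans(sq) ~ D[pairs])
  expect_gt(coef(fit)[2], 0)
  # BM theory: slope of E[(dz)^2] on distance is sigma^2 = 1
  expect_lt(abs(coef(fit)[2] - 1), 0.35)

  expect_identical(simulate_trait(tree2, seed = 4), simulate_trait(tree2, seed = 4))
})

test_that("simulated counts have multinomial totals and are deterministic", {
  cfg <- synth_config(n_taxa = 60, group_sizes = c(a = 4, b = 4),
                      n_blocks = 2, block_size = 8, depth_range = c(500, 900),
                      seed = 11)
  sim1 <- simulate_dataset(cfg)
  sim2 <- simulate_dataset(cfg)
  expect_identical(sim1$table$counts, sim2$table$counts)
  expect_identical(ape::write.tree(sim1$tree), ape::write.tree(sim2$tree))
  expect_identical(sim1$truth$block_of, sim2$truth$block_of)

  sums <- colSums(sim1$table$counts)
  expect_true(all(sums >= 500 & sums <= 900))   # every depth in range
  expect_true(all(sums > 0))                    # no all-zero samples
  expect_true(all(sim1$table$counts >= 0))
  expect_identical(storage.mode(sim1$table$counts), "integer")

  # ground-truth invariants
  expect_true(all(sim1$truth$hub_taxa %in%
                    names(which(!is.na(sim1$truth$block_of)))))
  expect_setequal(names(sim1$truth$regime), c("a", "b"))
  expect_identical(unname(sim1$truth$regime["a"]), "neutral")
})

test_that("without latent blocks or filtering, pairwise correlations are null", {
  # Monte-Carlo check: mean across-replicate Spearman between two fixed
  # taxa is approximately zero
  vals <- vapply(1:100, function(r) {
    cfg <- synth_config(n_taxa = 150, group_sizes = c(a = 10),
                        n_blocks = 1, block_size = 5, hub_per_block = 0,
                        latent_strength = 0, filtering_strength = 0,
                        occupancy = 1, depth_range = c(2000, 4000), seed = r)
    sim <- simulate_dataset(cfg)
    m <- sim$table$counts
    # a mid-abundance pair: always detected, and not subject to the
    # compositional closure that couples the most dominant taxa
    o <- order(rowSums(m), decreasing = TRUE)
    cor(m[o[10], ], m[o[11], ], method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("planted blocks carry strong within-block rank correlation", {
  # generator calibration: 40 samples, latent 0.9, blocks of 15
  cfg <- synth_config(group_sizes = c(all = 40), filtering_strength = 0,
                      occupancy = 1, seed = 7)
  sim <- simulate_dataset(cfg)
  rel <- relative_abundance(sim$table)
  truth <- sim$truth
  members <- names(truth$block_of)[!is.na(truth$block_of) &
                                     !(names(truth$block_of) %in% truth$hub_taxa)]
  rhos <- c()
  for (b in 1:4) {
    mb <- members[truth$block_of[members] == b]
    cm <- cor(t(rel[mb, ]), method = "spearman")
    rhos <- c(rhos, abs(cm[upper.tri(cm)]))
  }
  expect_gt(median(rhos), 0.6)
})

test_that("strong filtering empties far-from-optimum taxa in selective groups", {
  cfg <- synth_config(seed = 5)   # default filtering strength, 3 groups
  sim <- simulate_dataset(cfg)
  truth <- sim$truth
  down <- sim$table$counts[, sim$table$metadata$group == "down"]
  background <- names(truth$block_of)[is.na(truth$block_of)]
  far <- background[abs(truth$trait[background] -
                          truth$optima[["down"]]) > 1]
  prevalence <- rowMeans(down[far, ] > 0)
  expect_lt(mean(prevalence), 0.05)
  # neutral group keeps the same taxa around
  ctrl <- sim$table$counts[, sim$table$metadata$group == "control"]
  expect_gt(mean(rowMeans(ctrl[far, ] > 0)), 0.3)
})

test_that("write_dataset round-trips the table and tree", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_taxa = 40, group_sizes = c(a = 3, b = 3),
                      n_blocks = 2, block_size = 5,
                      depth_range = c(300, 500), seed = 2)
  sim <- simulate_dataset(cfg)
  paths <- write_dataset(sim, dir)
  expect_true(all(file.exists(paths)))
  meta <- read_sample_metadata(paths["metadata"])
  back <- read_count_table(paths["counts"], metadata = meta)
  expect_identical(back$counts, sim$table$counts)
  tree <- ape::read.tree(paths["tree"])
  expect_setequal(tree$tip.label, sim$tree$tip.label)
  truth <- jsonlite::read_json(paths["truth"])
  expect_named(truth, c("block_of", "hub_taxa", "hub_blocks", "trait",
                        "optima", "regime"), ignore.order = TRUE)
})

test_that("config invariants are enforced", {
  expect_error(synth_config(n_taxa = 10, n_blocks = 3, block_size = 5),
               class = "soilnet_invalid_argument")
  expect_error(synth_config(group_sizes = c(a = 1, b = 5)),
               class = "soilnet_invalid_argument")
  expect_error(synth_config(depth_range = c(100, 50)),
               class = "soilnet_invalid_argument")
  expect_error(synth_config(latent_strength = 1.2),
               class = "soilnet_invalid_argument")
  cfg <- synth_config(n_taxa = 20, n_blocks = 2, block_size = 5)
  tree <- simulate_tree(30, seed = 1)
  expect_error(simulate_counts(cfg, tree, simulate_trait(tree)),
               class = "soilnet_invalid_argument")
})
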