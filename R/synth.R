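#' Configuration for the synthetic amplicon-data generator
#'
#' The generator emulates the statistical structure the downstream pipeline
#' assumes: a multi-group field design with uneven sequencing depths,
#' heavy-tailed (log-normal) taxon abundances, planted blocks of
#' rank-correlated taxa that should surface as network modules, designated
#' hub taxa bridging several blocks, and a phylogenetically conserved
#' habitat-filtering signal of tunable strength that drives assembly from
#' stochastic towards homogeneous selection.
#'
#' Defaults mirror a 43-sample, three-arm soil survey (11 control + 16 + 16
#' treated samples) with 300 taxa, four planted 15-taxon blocks with one hub
#' each, strong within-block correlation (0.9), strong clade-level habitat
#' filtering in the treated arms, and library sizes uniform on 20,000-60,000.
#'
#' @param n_taxa Number of taxa (tree tips).
#' @param group_sizes Named integer vector, samples per group; the first
#'   group is assembled neutrally, later groups under homogeneous selection.
#' @param depth_range Length-2 vector, min and max library size.
#' @param n_blocks,block_size Planted correlation blocks and taxa per block.
#' @param hub_per_block Planted hub taxa per block.
#' @param latent_strength Within-block correlation of log-propensities, in
#'   `[0, 1]`.
#' @param filtering_strength Habitat-filtering selection strength (>= 0) on
#'   the standardized trait axis; the Gaussian niche width is
#'   `1/sqrt(2 * filtering_strength)` trait standard deviations, so the
#'   default 200 confines a selective group to a narrow band of clades
#'   (strong homogeneous selection); 0 disables filtering everywhere.
#' @param occupancy Per-sample probability that a background (non-block)
#'   taxon is available to colonize the sample (a dispersal lottery that
#'   creates the sample-to-sample membership turnover real communities
#'   show). Block and hub taxa are treated as persistent core taxa and are
#'   always available. Taxon-level rates are
#'   heterogeneous (a persistent core plus harder-flickering satellites)
#'   averaging to this value. Default 0.5.
#' @param seed Master seed for the generator.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_taxa = 300,
                         group_sizes = c(control = 11, down = 16, mid = 16),
                         depth_range = c(20000, 60000),
                         n_blocks = 4,
                         block_size = 15,
                         hub_per_block = 1,
                         latent_strength = 0.9,
                         filtering_strength = 200,
                         occupancy = 0.5,
                         seed = 1L) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    abort_invalid("`group_sizes` must be a named vector of group sizes")
  }
  if (any(group_sizes < 2)) abort_invalid("every group needs >= 2 samples")
  if (n_blocks * block_size > n_taxa) {
    abort_invalid("n_blocks * block_size must not exceed n_taxa")
  }
  if (depth_range[1] > depth_range[2] || depth_range[1] < 1) {
    abort_invalid("`depth_range` must satisfy 1 <= min <= max")
  }
  if (latent_strength < 0 || latent_strength > 1) {
    abort_invalid("`latent_strength` must lie in [0, 1]")
  }
  if (filtering_strength < 0) abort_invalid("`filtering_strength` must be >= 0")
  if (occupancy <= 0 || occupancy > 1) {
    abort_invalid("`occupancy` must lie in (0, 1]")
  }
  if (hub_per_block < 0 || hub_per_block > block_size) {
    abort_invalid("`hub_per_block` must lie in [0, block_size]")
  }
  structure(list(n_taxa = as.integer(n_taxa),
                 group_sizes = group_sizes,
                 depth_range = depth_range,
                 n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 hub_per_block = as.integer(hub_per_block),
                 latent_strength = latent_strength,
                 filtering_strength = filtering_strength,
                 occupancy = occupancy,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate a random rooted phylogeny
#'
#' A rooted, bifurcating tree with positive branch lengths and tip labels
#' `taxon_0001`, ..., matching the taxon ids of simulated count tables.
#' The topology is two-level, mimicking the deep clade structure of
#' microbial phylogenies: a random backbone of roughly `n_taxa / 4` deep
#' lineages (long basal branches) each carrying a shallow terminal crown
#' (short branches). Traits evolved on such a tree by Brownian motion are
#' strongly conserved within crowns, so habitat filtering on the trait
#' selects whole clades - the structure the nearest-taxon index responds
#' to.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed; the Newick string is reproducible.
#' @param crown_scale Branch-length scale of the terminal crowns relative
#'   to the backbone. Default 0.03.
#' @return An [ape::phylo] object.
#' @export
simulate_tree <- function(n_taxa, seed = 1L, crown_scale = 0.03) {
  if (n_taxa < 2) abort_invalid("`n_taxa` must be >= 2")
  tree <- withr::with_seed(as.integer(seed), {
    k <- max(2L, min(as.integer(ceiling(n_taxa / 4)), n_taxa %/% 2L))
    sizes <- rep(n_taxa %/% k, k)
    extra <- n_taxa - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    backbone <- ape::rtree(k)
    backbone$edge.length <- backbone$edge.length + 0.5  # long deep branches
    backbone$tip.label <- sprintf("clade%03d", seq_len(k))
    out <- backbone
    for (i in seq_len(k)) {
      if (sizes[i] == 1L) next
      crown <- ape::rtree(sizes[i])
      crown$edge.length <- crown$edge.length * crown_scale
      crown$tip.label <- sprintf("tmp%03d_%04d", i, seq_len(sizes[i]))
      out <- ape::bind.tree(out, crown,
                            where = which(out$tip.label ==
                                            sprintf("clade%03d", i)))
    }
    out
  })
  tree$tip.label <- sprintf("taxon_%04d", seq_len(ape::Ntip(tree)))
  tree
}

#' Simulate a phylogenetically conserved trait
#'
#' Evolves a continuous trait along the tree under Brownian motion:
#' independent zero-mean increments with variance proportional to branch
#' length, so closely related tips carry correlated trait values. This is
#' the signal that habitat filtering acts on and that the beta nearest
#' taxon index is designed to detect.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @param seed Integer seed.
#' @param sigma Brownian rate (trait standard deviation per unit branch
#'   length). Default 1.
#' @return A named numeric vector of trait values, one per tip.
#' @export
simulate_trait <- function(tree, seed = 1L, sigma = 1) {
  withr::with_seed(as.integer(seed),
    ape::rTraitCont(tree, model = "BM", sigma = sigma))
}

hub_block_span <- function(block, n_blocks) {
  # hubs load on every block: participation then spreads over all modules,
  # which keeps the participation coefficient robustly above the connector
  # threshold even when some blocks contribute few edges
  seq_len(n_blocks)
}

#' Simulate a count table with known ground truth
#'
#' Per sample, taxon propensities are built as
#' log-normal base abundance x correlated latent block factor x habitat
#' filter, and counts are drawn multinomially at a depth uniform over
#' `depth_range`. Block members share a per-sample latent factor with
#' loading `sqrt(latent_strength)`, which induces within-block correlation
#' `latent_strength` of log-propensities. Hub taxa are noise-free
#' combinations of three block factors (the block factors themselves share
#' a weak global factor), so hubs correlate with members of several blocks
#' and surface as connectors in the recovered network. Groups after the
#' first are assembled under homogeneous selection: taxon propensities are
#' down-weighted by `exp(-filtering_strength * (trait - optimum)^2)` on the
#' standardized trait axis, with group optima equally spaced over the trait
#' distribution.
#'
#' @param config A [synth_config()].
#' @param tree Phylogeny whose tips are the taxa (from [simulate_tree()]).
#' @param traits Named trait vector covering all tips (from
#'   [simulate_trait()]).
#' @return A list with `table` (an [asv_table()]) and `truth`, a list with
#'   `block_of` (named integer, `NA` outside blocks), `hub_taxa`,
#'   `hub_blocks`, `trait` (standardized), `optima`, and `regime` (named by
#'   group: `"neutral"` or `"homogeneous_selection"`).
#' @export
simulate_counts <- function(config, tree, traits) {
  stopifnot(inherits(config, "synth_config"))
  taxa <- tree$tip.label
  if (length(taxa) != config$n_taxa) {
    abort_invalid(sprintf("tree has %d tips but config expects %d taxa",
                          length(taxa), config$n_taxa))
  }
  if (!all(taxa %in% names(traits))) {
    abort_invalid("`traits` must cover every tree tip")
  }
  n <- config$n_taxa
  groups <- names(config$group_sizes)
  n_samples <- sum(config$group_sizes)
  group_of <- rep(groups, config$group_sizes)
  sample_ids <- sprintf("%s_%02d", group_of,
                        unlist(lapply(config$group_sizes, seq_len)))
  regime <- setNames(c("neutral",
                       rep("homogeneous_selection", length(groups) - 1L)),
                     groups)

  z <- scale(traits[taxa])[, 1]        # standardized trait axis
  selective <- groups[regime == "homogeneous_selection"]
  optima <- if (length(selective)) {
    setNames(as.numeric(quantile(z, probs = seq_along(selective) /
                                   (length(selective) + 1))), selective)
  } else {
    setNames(numeric(0), character(0))
  }

  seeds <- derive_seeds(config$seed, 8L)
  base <- withr::with_seed(seeds[1], rlnorm(n, meanlog = 0, sdlog = 1.5))

  block_taxa <- withr::with_seed(seeds[2],
    sample(taxa, config$n_blocks * config$block_size))
  block_of <- setNames(rep(NA_integer_, n), taxa)
  block_of[block_taxa] <- rep(seq_len(config$n_blocks),
                              each = config$block_size)
  hub_taxa <- unlist(lapply(seq_len(config$n_blocks), function(b) {
    block_taxa[block_of[block_taxa] == b][seq_len(config$hub_per_block)]
  }))
  hub_blocks <- lapply(setNames(block_of[hub_taxa], hub_taxa),
                       hub_block_span, n_blocks = config$n_blocks)
  base[match(hub_taxa, taxa)] <- base[match(hub_taxa, taxa)] * 5

  # per-sample latent structure: weakly correlated block factors (shared
  # global factor, pairwise correlation tau) plus idiosyncratic noise;
  # tau trades hub-member correlation (must clear the edge threshold)
  # against cross-block member correlation (must stay well below it)
  tau <- 0.44
  sigma_s <- 1.35  # per-sample log-abundance fluctuation scale
  lambda <- config$latent_strength
  latent_parts <- withr::with_seed(seeds[3], {
    g <- rnorm(n_samples)
    eta <- matrix(rnorm(config$n_blocks * n_samples), config$n_blocks)
    zf <- sqrt(tau) * rep(g, each = config$n_blocks) + sqrt(1 - tau) * eta
    dim(zf) <- c(config$n_blocks, n_samples)
    list(g = g, zf = zf)
  })
  latent_g <- latent_parts$g
  latent <- latent_parts$zf
  eps <- withr::with_seed(seeds[4], matrix(rnorm(n * n_samples), n))

  u <- sqrt(1 - lambda) * eps            # idiosyncratic share
  is_member <- !is.na(block_of)
  if (lambda > 0 && any(is_member)) {
    u[is_member, ] <- u[is_member, ] +
      sqrt(lambda) * latent[block_of[is_member], , drop = FALSE]
  }
  # background taxa carry a weak negative loading on the global factor;
  # this keeps the per-sample propensity total roughly orthogonal to the
  # latent factors, so compositional closure does not cancel the planted
  # correlation signal of multi-block hubs
  bg_load <- 0.28 * sqrt(lambda)
  g_row <- matrix(rep(latent_g, each = sum(!is_member)), sum(!is_member))
  u[!is_member, ] <- sqrt(1 - bg_load^2) * eps[!is_member, , drop = FALSE] -
    bg_load * g_row
  for (h in hub_taxa) {                  # hubs: almost pure multi-block load
    span <- hub_blocks[[h]]
    denom <- sqrt(length(span) + tau * length(span) * (length(span) - 1))
    combo <- colSums(latent[span, , drop = FALSE]) / denom
    u[match(h, taxa), ] <- sqrt(0.98) * combo +
      sqrt(0.02) * eps[match(h, taxa), ]
  }

  log_prop <- log(base) + sigma_s * u
  # habitat filtering penalizes trait distance from the group optimum; in
  # the same selective groups, taxa near the optimum additionally share a
  # per-sample environmental factor, so strongly selected communities
  # develop their own co-occurrence structure (selection both filters and
  # synchronizes the survivors)
  filt <- matrix(0, n, n_samples)
  if (config$filtering_strength > 0 && length(selective)) {
    niche_w <- 1 / sqrt(2 * config$filtering_strength)
    env <- withr::with_seed(seeds[7], rnorm(n_samples))
    for (g in selective) {
      idx <- which(group_of == g)
      filt[, idx] <- -config$filtering_strength * (z - optima[[g]])^2
      loading <- 2.5 * exp(-(z - optima[[g]])^2 / (2 * (2 * niche_w)^2))
      log_prop[, idx] <- log_prop[, idx] + sigma_s * (loading %o% env[idx])
    }
  }
  prop <- exp(log_prop + filt)

  # dispersal lottery: background taxa are absent from a sample with
  # probability 1 - occupancy, independent of abundance; this produces the
  # membership turnover between replicate samples that the nearest-taxon
  # null model needs in order to see clade-confined communities
  if (config$occupancy < 1) {
    avail <- withr::with_seed(seeds[8], {
      # core/satellite occupancy structure: a persistent fraction of the
      # background taxa is always available, the rest flicker harder, with
      # the per-taxon rates averaging to `occupancy`
      persistent_frac <- 0.25
      q_flicker <- max(0, (config$occupancy - persistent_frac) /
                         (1 - persistent_frac))
      q_taxon <- ifelse(runif(n) < persistent_frac, 1, q_flicker)
      matrix(rbinom(n * n_samples, 1L,
                    rep(q_taxon, n_samples)), n)
    })
    avail[is_member, ] <- 1L
    prop <- prop * avail
  }

  depths <- withr::with_seed(seeds[5],
    round(runif(n_samples, config$depth_range[1], config$depth_range[2])))
  counts <- withr::with_seed(seeds[6], {
    m <- vapply(seq_len(n_samples),
                function(s) rmultinom(1, depths[s], prop[, s])[, 1],
                integer(n))
    dimnames(m) <- list(taxa, sample_ids)
    m
  })

  table <- asv_table(counts,
                     tibble::tibble(sample_id = sample_ids, group = group_of))
  truth <- list(block_of = block_of, hub_taxa = hub_taxa,
                hub_blocks = hub_blocks, trait = z, optima = optima,
                regime = regime)
  list(table = table, truth = truth)
}

#' Simulate a complete synthetic dataset
#'
#' Runs [simulate_tree()], [simulate_trait()] and [simulate_counts()] under
#' seeds derived from `config$seed`, and assigns clade-based phylum labels
#' so phylum-level aggregation can be exercised.
#'
#' @param config A [synth_config()].
#' @param n_phyla Number of clade-based phylum labels. Default 8.
#' @return A list with `table`, `tree`, `traits`, `truth`, `taxonomy`
#'   (tibble `taxon_id`, `phylum`) and `config`.
#' @export
simulate_dataset <- function(config = synth_config(), n_phyla = 8) {
  seeds <- derive_seeds(config$seed + 1L, 2L)
  tree <- simulate_tree(config$n_taxa, seed = seeds[1])
  traits <- simulate_trait(tree, seed = seeds[2])
  sim <- simulate_counts(config, tree, traits)
  cl <- stats::cutree(stats::hclust(stats::as.dist(ape::cophenetic.phylo(tree)),
                                    method = "average"),
                      k = min(n_phyla, config$n_taxa))
  taxonomy <- tibble::tibble(taxon_id = names(cl),
                             phylum = sprintf("Phylum_%02d", cl))
  c(sim, list(tree = tree, traits = traits, taxonomy = taxonomy,
              config = config))
}

#' Write a synthetic dataset to disk
#'
#' Writes the count table and metadata as TSV, the tree as Newick, the
#' taxonomy as TSV, and the ground truth as JSON.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             tree = file.path(dir, "tree.nwk"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "truth.json"))
  write_count_table(sim$table, paths["counts"])
  write_sample_metadata(sim$table$metadata, paths["metadata"])
  ape::write.tree(sim$tree, paths["tree"])
  write.table(sim$taxonomy, paths["taxonomy"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- sim$truth
  truth$hub_blocks <- lapply(truth$hub_blocks, as.integer)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = FALSE,
                       digits = NA, na = "null")
  invisible(paths)
}
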