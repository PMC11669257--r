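#' Pipeline configuration
#'
#' Collects every tunable of the full analysis chain with the conventional
#' defaults: prevalence 0.5, Spearman `|rho| > 0.6` with BH `p < 0.05`,
#' Zi/Pi role cuts 2.5/0.62, betaNTI cut 2, 50% random removal, five
#' targeted hubs, 100 robustness replicates, 999 null replicates and 999
#' permutations. Input is either a [synth_config()] (`simulate`) or paths
#' to a count table, metadata and Newick tree.
#'
#' @param simulate A [synth_config()], or `NULL` to read from paths.
#' @param counts_path,metadata_path,tree_path Input files when not
#'   simulating.
#' @param groups Optional subset of group labels to analyse (validated
#'   against the metadata before any computation).
#' @param prevalence,r_min,alpha,zi_cut,pi_cut,bnti_cut,remove_fraction
#'   Thresholds (see module functions).
#' @param n_hubs,n_reps,n_null,n_permutations Simulation sizes.
#' @param rarefaction_depth `NULL` for the minimum library size.
#' @param seed Master seed; stage seeds are derived from it in a fixed
#'   order (rarefaction, ordination/PERMANOVA, betaNTI, stability).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = synth_config(),
                            counts_path = NULL, metadata_path = NULL,
                            tree_path = NULL, groups = NULL,
                            prevalence = 0.5, r_min = 0.6, alpha = 0.05,
                            zi_cut = 2.5, pi_cut = 0.62, bnti_cut = 2,
                            remove_fraction = 0.5, n_hubs = 5, n_reps = 100,
                            n_null = 999, n_permutations = 999,
                            rarefaction_depth = NULL, seed = 1L) {
  thresholds <- c(prevalence = prevalence, r_min = r_min, alpha = alpha,
                  zi_cut = zi_cut, pi_cut = pi_cut, bnti_cut = bnti_cut,
                  remove_fraction = remove_fraction)
  if (any(thresholds <= 0)) {
    abort_invalid(sprintf("thresholds must be positive; offending: %s",
                          paste(names(thresholds)[thresholds <= 0],
                                collapse = ", ")))
  }
  structure(list(simulate = simulate, counts_path = counts_path,
                 metadata_path = metadata_path, tree_path = tree_path,
                 groups = groups, prevalence = prevalence, r_min = r_min,
                 alpha = alpha, zi_cut = zi_cut, pi_cut = pi_cut,
                 bnti_cut = bnti_cut, remove_fraction = remove_fraction,
                 n_hubs = n_hubs, n_reps = n_reps, n_null = n_null,
                 n_permutations = n_permutations,
                 rarefaction_depth = rarefaction_depth,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage,
                         conditionMessage(e)),
                 class = "soilnet_stage_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/read -> rarefy -> alpha diversity -> weighted
#' UniFrac + PCoA + PERMANOVA -> betaNTI assembly classification ->
#' per-group co-occurrence networks -> module detection and Zi/Pi roles ->
#' robustness and vulnerability, all under seeds derived from the master
#' seed, and assembles a machine-readable summary. Re-running with the
#' same config reproduces every number exactly.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `soilnet_pipeline` with elements `table`
#'   (rarefied), `tree`, `alpha`, `unifrac`, `ordination`, `permanova`,
#'   `bnti`, `bnti_by_group`, `networks`, `modules`, `roles`, `keystones`,
#'   `stability`, `topology`, `truth` (when simulated) and `summary`
#'   (plain named list, JSON-ready).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 4L)

  data <- with_stage("input", {
    if (!is.null(config$simulate)) {
      sim <- simulate_dataset(config$simulate)
      list(table = sim$table, tree = sim$tree, truth = sim$truth)
    } else {
      meta <- read_sample_metadata(config$metadata_path)
      list(table = read_count_table(config$counts_path, metadata = meta),
           tree = ape::read.tree(config$tree_path), truth = NULL)
    }
  })
  groups <- unique(data$table$metadata$group)
  if (!is.null(config$groups)) {
    unknown <- setdiff(config$groups, groups)
    if (length(unknown)) {
      abort_invalid(sprintf("unknown group label(s) in config: %s",
                            paste(unknown, collapse = ", ")))
    }
    keep <- data$table$metadata$sample_id[
      data$table$metadata$group %in% config$groups]
    data$table <- subset_samples_tab(data$table, keep)
    groups <- config$groups
  }

  rarefied <- with_stage("rarefaction",
    rarefy_counts(data$table, depth = config$rarefaction_depth,
                  seed = seeds[1]))
  alpha <- with_stage("alpha_diversity", alpha_diversity(rarefied))
  uf <- with_stage("weighted_unifrac",
    weighted_unifrac(rarefied, data$tree, normalized = TRUE))
  ord <- with_stage("pcoa", pcoa_ordination(uf, rarefied$metadata))
  perma <- with_stage("permanova",
    permanova(uf, rarefied$metadata, n_permutations = config$n_permutations,
              seed = seeds[2]))
  bn <- with_stage("bnti",
    bnti(rarefied, data$tree, n_null = config$n_null, seed = seeds[3],
         comparisons = "within", bnti_cut = config$bnti_cut))
  bn_groups <- bnti_group_summary(bn)

  networks <- list(); modules <- list(); roles <- list()
  topology <- list(); stability <- list()
  stage_seed <- seeds[4]
  for (g in groups) {
    net <- with_stage(paste0("network:", g),
      group_network(rarefied, g, min_fraction = config$prevalence,
                    r_min = config$r_min, alpha = config$alpha))
    networks[[g]] <- net
    if (igraph::ecount(net) == 0) {
      # a strongly selected, small community can yield no retained edges;
      # record the group as an empty network rather than failing the run
      rlang::warn(sprintf("group '%s' yields an empty network", g))
      topology[[g]] <- list(
        nodes = tibble::tibble(node = character(), degree = integer(),
                               weighted_degree = numeric(),
                               betweenness = numeric(),
                               eigenvector = numeric()),
        network = tibble::tibble(n_nodes = 0L, n_edges = 0L,
                                 density = NA_real_, mean_degree = NA_real_,
                                 centralization_betweenness = NA_real_,
                                 centralization_eigenvector = NA_real_))
      next
    }
    part <- with_stage(paste0("modules:", g), detect_modules(net))
    modules[[g]] <- part
    rl <- with_stage(paste0("roles:", g),
      zi_pi(net, part, zi_cut = config$zi_cut, pi_cut = config$pi_cut))
    roles[[g]] <- dplyr::mutate(rl, group = g, .before = 1)
    topology[[g]] <- with_stage(paste0("topology:", g),
                                topology_metrics(net))
    if (igraph::vcount(net) < 3) {
      # too small for removal simulations and vulnerability; recorded as
      # missing in the summary
      rlang::warn(sprintf(
        "group '%s' network has fewer than 3 nodes; stability skipped", g))
    } else {
      stability[[g]] <- with_stage(paste0("stability:", g),
        stability_report(net, rl, remove_fraction = config$remove_fraction,
                         n_hubs = min(config$n_hubs,
                                      igraph::vcount(net) - 1L),
                         n_reps = config$n_reps,
                         seed = stage_seed + match(g, groups)))
    }
  }
  keystones <- if (length(roles)) {
    keystone_summary(dplyr::bind_rows(roles))
  } else {
    tibble::tibble(group = character(), peripheral = integer(),
                   connector = integer(), module_hub = integer(),
                   network_hub = integer(), n_nodes = integer(),
                   keystone = integer())
  }

  summary <- pipeline_summary(groups, alpha, perma, bn_groups, networks,
                              topology, keystones, stability, config)
  structure(list(table = rarefied, tree = data$tree, truth = data$truth,
                 alpha = alpha, unifrac = uf, ordination = ord,
                 permanova = perma, bnti = bn, bnti_by_group = bn_groups,
                 networks = networks, modules = modules,
                 roles = dplyr::bind_rows(roles), keystones = keystones,
                 topology = topology, stability = stability,
                 summary = summary, config = config),
            class = "soilnet_pipeline")
}

pipeline_summary <- function(groups, alpha, perma, bn_groups, networks,
                             topology, keystones, stability, config) {
  per_group <- lapply(setNames(groups, groups), function(g) {
    st <- stability[[g]]
    ks <- keystones[!is.na(keystones$group) & keystones$group == g, ]
    empty <- nrow(ks) == 0
    net_row <- topology[[g]]$network
    a <- alpha[alpha$group == g, ]
    list(
      n_samples = nrow(a),
      mean_richness = mean(a$richness),
      mean_shannon = mean(a$shannon),
      n_nodes = net_row$n_nodes,
      n_edges = net_row$n_edges,
      density = net_row$density,
      mean_degree = net_row$mean_degree,
      centralization_betweenness = net_row$centralization_betweenness,
      centralization_eigenvector = net_row$centralization_eigenvector,
      connectors = if (empty) 0L else ks$connector,
      module_hubs = if (empty) 0L else ks$module_hub,
      network_hubs = if (empty) 0L else ks$network_hub,
      keystones = if (empty) 0L else ks$keystone,
      bnti = as.list(bn_groups[bn_groups$group == g,
                               c("n_pairs", "mean_bnti", "stochastic",
                                 "homogeneous_selection",
                                 "heterogeneous_selection",
                                 "deterministic")]),
      robustness_random_mean = if (is.null(st)) NA_real_ else
        mean(st$robustness_random$robustness),
      robustness_random_se = if (is.null(st)) NA_real_ else
        sd(st$robustness_random$robustness) /
          sqrt(nrow(st$robustness_random)),
      robustness_targeted_mean = if (is.null(st)) NA_real_ else
        mean(st$robustness_targeted$robustness),
      targeted_fallback = if (is.null(st)) NA_integer_ else
        st$settings$targeted_fallback,
      vulnerability = if (is.null(st)) NA_real_ else
        st$vulnerability_network)
  })
  list(
    groups = per_group,
    permanova = list(pseudo_F = perma$pseudo_F, R2 = perma$R2,
                     p_value = perma$p_value, df_between = perma$df_between,
                     df_within = perma$df_within,
                     n_permutations = perma$n_permutations),
    thresholds = list(prevalence = config$prevalence, r_min = config$r_min,
                      alpha = config$alpha, zi_cut = config$zi_cut,
                      pi_cut = config$pi_cut, bnti_cut = config$bnti_cut,
                      remove_fraction = config$remove_fraction,
                      n_hubs = config$n_hubs, n_reps = config$n_reps,
                      n_null = config$n_null,
                      n_permutations = config$n_permutations),
    seed = config$seed)
}

#' @export
print.soilnet_pipeline <- function(x, ...) {
  cat(sprintf("<soilnet_pipeline> %d taxa x %d samples, groups: %s\n",
              nrow(x$table$counts), ncol(x$table$counts),
              paste(names(x$networks), collapse = ", ")))
  print(x$permanova)
  print(x$bnti_by_group)
  invisible(x)
}

#' Write the pipeline summary as JSON
#'
#' @param result A `soilnet_pipeline` result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_summary <- function(result, path) {
  jsonlite::write_json(result$summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
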