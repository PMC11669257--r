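#' Spearman co-occurrence edges
#'
#' Tests every taxon pair for Spearman rank correlation of relative
#' abundances across samples (average ranks for ties), adjusts the
#' p-values once across all tested pairs with Benjamini-Hochberg, and
#' retains edges with `|rho| > r_min` and adjusted `p < alpha` (the
#' conventional `|r| > 0.6`, BH `p < 0.05` rule). P-values use the
#' t-approximation for n >= 10 samples and the exact tie-free null
#' distribution for smaller n. Taxa constant across samples have no
#' defined rank correlation; their pairs are skipped with a warning.
#'
#' @param rel_abundance A taxa-by-samples matrix of relative abundances
#'   (see [relative_abundance()]) or an [asv_table()].
#' @param r_min Correlation magnitude threshold (edges require
#'   `|rho| > r_min`). Default 0.6.
#' @param alpha BH-adjusted significance threshold. Default 0.05.
#' @return A tibble of retained edges: `from`, `to`, `rho`, `p_value`,
#'   `p_adjusted`, `weight` (= `|rho|`), `sign`. The full set of tested
#'   pairs is kept in attribute `"tested"`.
#' @export
spearman_edges <- function(rel_abundance, r_min = 0.6, alpha = 0.05) {
  m <- if (inherits(rel_abundance, "asv_table")) {
    relative_abundance(rel_abundance)
  } else {
    as.matrix(rel_abundance)
  }
  n <- ncol(m)
  if (n < 4) abort_invalid("need at least 4 samples for correlation testing")
  constant <- apply(m, 1, function(v) length(unique(v)) == 1L)
  if (any(constant)) {
    rlang::warn(sprintf(
      "%d constant taxa have undefined correlations; their pairs are skipped",
      sum(constant)))
    m <- m[!constant, , drop = FALSE]
  }
  if (nrow(m) < 2) {
    return(empty_edge_tibble())
  }
  rho <- cor(t(m), method = "spearman")
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  p <- if (n >= 10) {
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    2 * pt(-abs(tstat), df = n - 2)
  } else {
    vapply(seq_len(nrow(idx)), function(k) {
      suppressWarnings(cor.test(m[idx[k, 1], ], m[idx[k, 2], ],
                                method = "spearman"))$p.value
    }, numeric(1))
  }
  p[abs(r) >= 1 - 1e-12] <- 0
  p_adj <- p.adjust(p, method = "BH")
  tested <- tibble::tibble(
    from = rownames(m)[idx[, 1]],
    to = rownames(m)[idx[, 2]],
    rho = r, p_value = p, p_adjusted = p_adj,
    weight = abs(r), sign = ifelse(r >= 0, "positive", "negative"))
  edges <- dplyr::filter(tested, abs(.data$rho) > r_min,
                         .data$p_adjusted < alpha)
  attr(edges, "tested") <- tested
  edges
}

empty_edge_tibble <- function() {
  tibble::tibble(from = character(), to = character(), rho = numeric(),
                 p_value = numeric(), p_adjusted = numeric(),
                 weight = numeric(), sign = character())
}

#' Build a co-occurrence network from an edge list
#'
#' Creates a simple undirected [igraph] graph with `rho`, `p_adjusted`,
#' `sign` and `weight = |rho|` edge attributes. Taxa with no retained edge
#' are excluded from the node set; duplicate orientations of the same pair
#' collapse to a single edge.
#'
#' @param edges Edge tibble from [spearman_edges()].
#' @param group Optional group label stored as a graph attribute.
#' @return An [igraph] graph.
#' @export
build_network <- function(edges, group = NULL) {
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "rho", "p_value", "p_adjusted", "weight", "sign")],
    directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = "first")
  if (!is.null(group)) g <- igraph::set_graph_attr(g, "group", group)
  g
}

#' Per-group co-occurrence network
#'
#' Convenience wrapper chaining the per-group prevalence filter, relative
#' abundances, [spearman_edges()] and [build_network()].
#'
#' @param table A rarefied [asv_table()].
#' @param group Group label.
#' @param min_fraction Prevalence threshold. Default 0.5.
#' @inheritParams spearman_edges
#' @return An [igraph] graph with graph attribute `group`.
#' @export
group_network <- function(table, group, min_fraction = 0.5, r_min = 0.6,
                          alpha = 0.05) {
  filtered <- filter_prevalence(table, group, min_fraction)
  edges <- spearman_edges(relative_abundance(filtered), r_min, alpha)
  build_network(edges, group = group)
}

#' Detect network modules
#'
#' Non-overlapping modules by greedy modularity maximization on edge
#' weights `|rho|`. The algorithm is deterministic for a fixed graph; the
#' `seed` argument is accepted for interface symmetry with the stochastic
#' stages. Modules with fewer than `minor_below` nodes are flagged minor
#' (they are still retained for Zi/Pi computation).
#'
#' @param network An [igraph] co-occurrence network with >= 1 edge.
#' @param seed Unused by the deterministic algorithm; kept for a stable
#'   calling convention.
#' @param minor_below Modules smaller than this are flagged minor.
#'   Default 5.
#' @return A tibble with columns `node`, `module`, `module_size`, `minor`.
#' @export
detect_modules <- function(network, seed = 1L, minor_below = 5) {
  if (igraph::vcount(network) == 0) abort_invalid("network is empty")
  if (igraph::ecount(network) == 0) abort_invalid("network has no edges")
  comm <- igraph::cluster_fast_greedy(network,
                                      weights = igraph::E(network)$weight)
  membership <- igraph::membership(comm)
  q <- igraph::modularity(network, membership,
                          weights = igraph::E(network)$weight)
  if (q <= 0) {
    # no partition beats the trivial one (e.g. a single clique)
    membership <- setNames(rep(1L, igraph::vcount(network)),
                           igraph::V(network)$name)
  }
  out <- tibble::tibble(node = names(membership),
                        module = as.integer(membership))
  sizes <- dplyr::count(out, .data$module, name = "module_size")
  out <- dplyr::left_join(out, sizes, by = "module")
  out$minor <- out$module_size < minor_below
  dplyr::arrange(out, .data$module, .data$node)
}

#' Node- and network-level topology metrics
#'
#' Per node: degree, weighted degree (sum of incident `|rho|`),
#' betweenness on unweighted shortest paths, and eigenvector centrality of
#' the largest connected component (0 elsewhere). Per network: density,
#' mean degree, and Freeman centralization of betweenness and of
#' eigenvector centrality (observed dispersion of the scores relative to
#' the maximum attainable on a graph of the same size).
#'
#' @param network An [igraph] co-occurrence network with >= 1 node.
#' @return A list with `nodes` (tibble: `node`, `degree`,
#'   `weighted_degree`, `betweenness`, `eigenvector`) and `network`
#'   (tibble: `n_nodes`, `n_edges`, `density`, `mean_degree`,
#'   `centralization_betweenness`, `centralization_eigenvector`).
#' @export
topology_metrics <- function(network) {
  if (igraph::vcount(network) == 0) abort_invalid("network is empty")
  g0 <- unweighted(network)
  deg <- igraph::degree(g0)
  wdeg <- igraph::strength(network, weights = igraph::E(network)$weight)
  btw <- igraph::betweenness(g0, directed = FALSE)

  comps <- igraph::components(g0)
  largest <- which.max(comps$csize)
  lcc <- igraph::induced_subgraph(g0, which(comps$membership == largest))
  ev <- setNames(rep(0, igraph::vcount(g0)), igraph::V(g0)$name)
  # ARPACK draws its start vector from the RNG; fix it so repeated runs
  # are bit-identical
  ev_lcc <- withr::with_seed(1L,
    igraph::eigen_centrality(lcc, directed = FALSE)$vector)
  ev[names(ev_lcc)] <- ev_lcc

  centr_b <- igraph::centr_betw(g0, directed = FALSE)$centralization
  centr_e <- withr::with_seed(1L,
    igraph::centr_eigen(lcc, directed = FALSE)$centralization)

  list(
    nodes = tibble::tibble(node = igraph::V(g0)$name,
                           degree = as.integer(deg),
                           weighted_degree = as.numeric(wdeg),
                           betweenness = as.numeric(btw),
                           eigenvector = as.numeric(ev)),
    network = tibble::tibble(
      n_nodes = igraph::vcount(g0),
      n_edges = igraph::ecount(g0),
      density = igraph::edge_density(g0),
      mean_degree = mean(deg),
      centralization_betweenness = centr_b,
      centralization_eigenvector = centr_e))
}

#' Write a network to disk
#'
#' @param network An [igraph] graph.
#' @param path Output path; format chosen by extension (`.graphml` or
#'   `.tsv` edge list with `source`, `target`, `rho`, `p_adjusted`,
#'   `weight`).
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path) {
  if (grepl("\\.graphml$", path)) {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    df <- igraph::as_data_frame(network, what = "edges")
    names(df)[1:2] <- c("source", "target")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
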