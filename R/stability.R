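#' Global efficiency
#'
#' Average inverse shortest-path distance over all node pairs,
#' \eqn{E = \frac{2}{n(n-1)} \sum_{i<j} 1/d_{ij}}, with unweighted
#' distances and disconnected pairs contributing 0.
#'
#' @param network An [igraph] graph with >= 2 nodes.
#' @return A single number in `[0, 1]`.
#' @export
global_efficiency <- function(network) {
  if (igraph::vcount(network) < 2) {
    abort_invalid("global efficiency needs at least 2 nodes")
  }
  igraph::global_efficiency(unweighted(network), directed = FALSE)
}

#' Node and network vulnerability
#'
#' The vulnerability of node i is the relative drop in global efficiency
#' when i is deleted, \eqn{V_i = (E - E_i)/E}, where \eqn{E_i} is the
#' global efficiency of the remaining (n-1)-node graph (with its own pair
#' count). \eqn{V_i} can be negative when removing a node raises average
#' efficiency. Network vulnerability is the maximum over nodes.
#'
#' @param network An [igraph] graph with >= 3 nodes.
#' @return A list with `nodes` (tibble: `node`, `vulnerability`) and
#'   `network` (the maximal node vulnerability).
#' @export
vulnerability <- function(network) {
  if (igraph::vcount(network) < 3) {
    abort_invalid("vulnerability needs at least 3 nodes")
  }
  g0 <- unweighted(network)
  e_full <- igraph::global_efficiency(g0, directed = FALSE)
  vuln <- vapply(igraph::V(g0)$name, function(v) {
    ei <- igraph::global_efficiency(igraph::delete_vertices(g0, v),
                                    directed = FALSE)
    (e_full - ei) / e_full
  }, numeric(1))
  list(nodes = tibble::tibble(node = names(vuln),
                              vulnerability = as.numeric(vuln)),
       network = max(vuln))
}

# Fraction of the original nodes that keep at least one edge after
# deleting `remove`; a node isolated by the removal counts as extinct
# (one pass suffices: deleting an isolated node changes no other degree).
surviving_fraction <- function(graph, remove) {
  left <- igraph::delete_vertices(graph, remove)
  sum(igraph::degree(left) > 0) / igraph::vcount(graph)
}

#' Robustness to random node removal
#'
#' Per replicate, removes `floor(remove_fraction * n)` uniformly chosen
#' nodes and scores robustness as the fraction of the original nodes that
#' still have at least one edge (species left with no partner are counted
#' as secondary extinctions).
#'
#' @param network An [igraph] graph with >= 2 nodes.
#' @param remove_fraction Fraction of nodes to remove, in (0, 1).
#'   Default 0.5.
#' @param n_reps Number of replicates. Default 100.
#' @param seed Integer seed.
#' @return A tibble with columns `replicate`, `robustness`.
#' @export
robustness_random <- function(network, remove_fraction = 0.5, n_reps = 100,
                              seed = 1L) {
  n <- igraph::vcount(network)
  if (n < 2) abort_invalid("network needs at least 2 nodes")
  if (remove_fraction <= 0 || remove_fraction >= 1) {
    abort_invalid("`remove_fraction` must lie in (0, 1)")
  }
  n_remove <- floor(remove_fraction * n)
  if (n_remove >= n) abort_invalid("removal would eliminate every node")
  g0 <- unweighted(network)
  rob <- withr::with_seed(as.integer(seed), vapply(seq_len(n_reps), function(r) {
    surviving_fraction(g0, sample(igraph::V(g0)$name, n_remove))
  }, numeric(1)))
  tibble::tibble(replicate = seq_len(n_reps), robustness = rob)
}

#' Robustness to targeted hub removal
#'
#' Removes the `n_hubs` highest-Zi nodes among those classified as module
#' hubs or network hubs; when the network has fewer hubs than `n_hubs`,
#' the remaining removals fall back to the next-highest-Zi nodes overall
#' (recorded in the `fallback` attribute). The removal set is
#' deterministic (ties broken by node id), so replicates differ only via
#' that ordering; the replicate vector is kept for symmetry with
#' [robustness_random()].
#'
#' @param network An [igraph] graph.
#' @param roles Role tibble from [zi_pi()].
#' @param n_hubs Number of hubs to remove (>= 1). Default 5.
#' @param n_reps Number of replicates. Default 100.
#' @return A tibble with columns `replicate`, `robustness`; attributes
#'   `removed` (node ids) and `fallback` (how many removals were not
#'   classified hubs).
#' @export
robustness_targeted <- function(network, roles, n_hubs = 5, n_reps = 100) {
  n <- igraph::vcount(network)
  if (n_hubs < 1) abort_invalid("`n_hubs` must be >= 1")
  if (n_hubs >= n) abort_invalid("`n_hubs` must be smaller than the node count")
  roles <- dplyr::arrange(roles, dplyr::desc(.data$zi), .data$node)
  hubs <- roles$node[roles$role %in% c("module_hub", "network_hub")]
  removed <- head(hubs, n_hubs)
  fallback <- n_hubs - length(removed)
  if (fallback > 0) {
    rest <- setdiff(roles$node, removed)
    removed <- c(removed, head(rest, fallback))
  }
  g0 <- unweighted(network)
  rob <- surviving_fraction(g0, removed)
  out <- tibble::tibble(replicate = seq_len(n_reps),
                        robustness = rep(rob, n_reps))
  attr(out, "removed") <- removed
  attr(out, "fallback") <- fallback
  out
}

#' Compare robustness replicate vectors between two networks
#'
#' Welch's two-sided t-test on the replicate robustness vectors; two
#' degenerate vectors with equal means are reported as no difference
#' (p = 1).
#'
#' @param replicates_a,replicates_b Numeric vectors (or tibbles from the
#'   robustness functions) of length >= 2.
#' @return A tibble with `estimate` (mean a - mean b), `t`, `df`,
#'   `p_value`.
#' @export
compare_robustness <- function(replicates_a, replicates_b) {
  a <- if (is.data.frame(replicates_a)) replicates_a$robustness else replicates_a
  b <- if (is.data.frame(replicates_b)) replicates_b$robustness else replicates_b
  if (length(a) < 2 || length(b) < 2) {
    abort_invalid("each replicate vector needs length >= 2")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble::tibble(estimate = mean(a) - mean(b),
                          t = if (same) 0 else Inf * sign(mean(a) - mean(b)),
                          df = NA_real_, p_value = if (same) 1 else 0))
  }
  ht <- t.test(a, b, alternative = "two.sided", var.equal = FALSE)
  tibble::tibble(estimate = mean(a) - mean(b),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Full stability report for one network
#'
#' Bundles random and targeted robustness with node and network
#' vulnerability.
#'
#' @inheritParams robustness_random
#' @inheritParams robustness_targeted
#' @return A list of class `stability_report` with `robustness_random`,
#'   `robustness_targeted`, `vulnerability_nodes`,
#'   `vulnerability_network`, and `settings`.
#' @export
stability_report <- function(network, roles, remove_fraction = 0.5,
                             n_hubs = 5, n_reps = 100, seed = 1L) {
  rr <- robustness_random(network, remove_fraction, n_reps, seed)
  rt <- robustness_targeted(network, roles, n_hubs, n_reps)
  vu <- vulnerability(network)
  structure(list(robustness_random = rr,
                 robustness_targeted = rt,
                 vulnerability_nodes = vu$nodes,
                 vulnerability_network = vu$network,
                 settings = list(remove_fraction = remove_fraction,
                                 n_hubs = n_hubs, n_reps = n_reps,
                                 seed = seed,
                                 targeted_fallback = attr(rt, "fallback"))),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> random robustness %.3f +/- %.3f | targeted %.3f | vulnerability %.4g\n",
              mean(x$robustness_random$robustness),
              sd(x$robustness_random$robustness) /
                sqrt(nrow(x$robustness_random)),
              mean(x$robustness_targeted$robustness),
              x$vulnerability_network))
  invisible(x)
}
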