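#' Within-module (Zi) and among-module (Pi) connectivity
#'
#' For each node, given a module partition: Zi is the z-score of the
#' node's number of links into its own module relative to that module's
#' nodes (population standard deviation; modules where all nodes have the
#' same within-module degree get Zi = 0), and Pi is the participation
#' coefficient \eqn{1 - \sum_t (k_{it}/k_i)^2} over modules t. Both use
#' unweighted edge counts.
#'
#' @param network An [igraph] co-occurrence network.
#' @param partition Module partition from [detect_modules()] (tibble with
#'   `node`, `module`) or a named module vector.
#' @param zi_cut,pi_cut Role thresholds. Defaults 2.5 and 0.62.
#' @return A tibble with columns `node`, `module`, `degree`, `zi`, `pi`,
#'   `role`.
#' @export
zi_pi <- function(network, partition, zi_cut = 2.5, pi_cut = 0.62) {
  if (is.data.frame(partition)) {
    partition <- setNames(partition$module, partition$node)
  }
  nodes <- igraph::V(network)$name
  if (!all(nodes %in% names(partition))) {
    abort_invalid("`partition` must cover every network node")
  }
  mods <- partition[nodes]
  adj <- igraph::as_adjacency_matrix(unweighted(network), sparse = FALSE)
  adj <- (adj > 0) * 1
  mod_ids <- sort(unique(mods))
  # k_links[i, t] = edges from node i into module t
  k_links <- vapply(mod_ids, function(t) {
    rowSums(adj[, mods == t, drop = FALSE])
  }, numeric(length(nodes)))
  if (is.null(dim(k_links))) k_links <- matrix(k_links, nrow = length(nodes))
  k_total <- rowSums(k_links)
  k_own <- k_links[cbind(seq_along(nodes), match(mods, mod_ids))]

  zi <- numeric(length(nodes))
  for (t in mod_ids) {
    members <- mods == t
    k <- k_own[members]
    s <- sqrt(mean((k - mean(k))^2))    # population sd over the module
    zi[members] <- if (s > 0) (k - mean(k)) / s else 0
  }
  pi <- 1 - rowSums((k_links / pmax(k_total, 1))^2)
  pi[k_total == 0] <- 0
  zi <- unname(zi); pi <- as.numeric(pi)
  tibble::tibble(node = nodes, module = unname(mods),
                 degree = as.integer(unname(k_total)), zi = zi, pi = pi,
                 role = classify_role(zi, pi, zi_cut, pi_cut))
}

#' Classify node roles from (Zi, Pi)
#'
#' Strict thresholds: module hubs have Zi > 2.5 and Pi < 0.62, connectors
#' Zi < 2.5 and Pi > 0.62, network hubs Zi > 2.5 and Pi > 0.62; every
#' other node (including values exactly on a boundary) is peripheral.
#' Module hubs, connectors and network hubs are collectively the keystone
#' nodes.
#'
#' @param zi,pi Numeric vectors of within-module connectivity and
#'   participation.
#' @param zi_cut,pi_cut Thresholds. Defaults 2.5 and 0.62.
#' @return Character vector over `{"peripheral", "connector",
#'   "module_hub", "network_hub"}`.
#' @export
classify_role <- function(zi, pi, zi_cut = 2.5, pi_cut = 0.62) {
  dplyr::case_when(
    zi > zi_cut & pi > pi_cut ~ "network_hub",
    zi > zi_cut & pi < pi_cut ~ "module_hub",
    zi < zi_cut & pi > pi_cut ~ "connector",
    TRUE ~ "peripheral")
}

#' Keystone-role counts
#'
#' @param roles A role tibble from [zi_pi()] (optionally with a `group`
#'   column, e.g. after row-binding several networks).
#' @return A tibble of counts per role (per group when present), with a
#'   `keystone` column counting all non-peripheral nodes.
#' @export
keystone_summary <- function(roles) {
  by <- intersect("group", names(roles))
  levels <- c("peripheral", "connector", "module_hub", "network_hub")
  roles$role <- factor(roles$role, levels = levels)
  out <- dplyr::count(roles, dplyr::across(dplyr::all_of(by)), .data$role,
                      .drop = FALSE, name = "n")
  out <- tidyr::pivot_wider(out, names_from = "role", values_from = "n",
                            values_fill = 0L)
  out$n_nodes <- out$peripheral + out$connector + out$module_hub +
    out$network_hub
  out$keystone <- out$n_nodes - out$peripheral
  out
}
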