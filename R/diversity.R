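#' Alpha diversity per sample
#'
#' Observed richness (taxa with count > 0) and the Shannon index
#' \eqn{H = -\sum_i p_i \ln p_i} (natural log) for every sample.
#'
#' @param table An [asv_table()].
#' @return A tibble with columns `sample_id`, `group`, `richness`,
#'   `shannon`.
#' @export
alpha_diversity <- function(table) {
  sums <- colSums(table$counts)
  if (any(sums == 0)) {
    abort_invalid(sprintf("zero-total sample(s): %s",
                          paste(colnames(table$counts)[sums == 0],
                                collapse = ", ")))
  }
  tibble::tibble(
    sample_id = sample_names(table),
    group = table$metadata$group,
    richness = as.integer(colSums(table$counts > 0)),
    shannon = as.numeric(vegan::diversity(t(table$counts), index = "shannon"))
  )
}

#' Weighted UniFrac dissimilarity
#'
#' Phylogeny-aware beta diversity: each branch is weighted by the absolute
#' difference in the fraction of each sample's abundance descending from
#' it, \eqn{\sum_b l_b |p_{Ab} - p_{Bb}|}; the normalized variant (default)
#' divides by \eqn{\sum_b l_b (p_{Ab} + p_{Bb})} so distances lie in
#' `[0, 1]`.
#'
#' @param table An [asv_table()] whose taxa are all tips of `tree`.
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @param normalized Use the normalized variant? Default `TRUE`.
#' @return A symmetric [stats::dist] distance matrix over samples.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  missing <- setdiff(taxa_names(table), tree$tip.label)
  if (length(missing)) {
    abort_invalid(sprintf("taxa absent from the tree: %s",
                          paste(head(missing, 5), collapse = ", ")))
  }
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(table$counts, taxa_are_rows = TRUE),
    phyloseq::phy_tree(ape::keep.tip(tree, taxa_names(table))))
  phyloseq::UniFrac(ps, weighted = TRUE, normalized = normalized)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling (double-centred eigendecomposition) of a
#' distance matrix, with axes ordered by decreasing eigenvalue and the
#' proportion of variance explained computed over positive eigenvalues.
#'
#' @param dm A [stats::dist] or symmetric distance matrix with sample ids.
#' @param groups Optional named group vector (or a metadata tibble with
#'   `sample_id` and `group`) joined onto the coordinates.
#' @return A list of class `pcoa_ordination` with `coordinates` (tibble:
#'   `sample_id`, `group` if given, `Axis.1`, `Axis.2`, ...),
#'   `eigenvalues`, and `prop_explained` (over positive eigenvalues).
#' @export
pcoa_ordination <- function(dm, groups = NULL) {
  m <- as.matrix(dm)
  if (!isSymmetric(unname(m), tol = 1e-8)) {
    abort_invalid("distance matrix must be symmetric")
  }
  n <- nrow(m)
  fit <- suppressWarnings(cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig), 1)
  coords <- fit$points
  if (is.null(coords) || ncol(coords) == 0) {
    coords <- matrix(0, n, 2, dimnames = list(rownames(m), NULL))
  }
  colnames(coords) <- paste0("Axis.", seq_len(ncol(coords)))
  prop <- if (any(pos)) eig[pos] / sum(eig[pos]) else numeric(0)
  out <- tibble::as_tibble(coords)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), out)
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      out <- dplyr::left_join(out, groups[, c("sample_id", "group")],
                              by = "sample_id")
    } else {
      out$group <- unname(groups[out$sample_id])
    }
    out <- dplyr::relocate(out, "group", .after = "sample_id")
  }
  structure(list(coordinates = out, eigenvalues = eig,
                 prop_explained = prop),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("<pcoa_ordination> %d samples\n", nrow(x$coordinates)))
  k <- min(3, length(x$prop_explained))
  if (k > 0) {
    cat("variance explained:",
        paste(sprintf("Axis.%d %.1f%%", seq_len(k),
                      100 * x$prop_explained[seq_len(k)]), collapse = ", "),
        "\n")
  }
  invisible(x)
}
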