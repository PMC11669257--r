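#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement down to a common
#' depth, the conventional correction for uneven library sizes before
#' diversity and network analysis. The default depth is the minimum library
#' size over samples.
#'
#' @param table An [asv_table()].
#' @param depth Target reads per sample; defaults to the minimum column sum.
#' @param seed Integer seed; identical seeds give identical rarefactions.
#' @return A rarefied [asv_table()] in which every column sums to `depth`.
#' @export
rarefy_counts <- function(table, depth = NULL, seed = 1L) {
  sums <- colSums(table$counts)
  depth <- depth %||% min(sums)
  assert_scalar_number(depth, "depth")
  low <- sums < depth
  if (any(low)) {
    abort_invalid(sprintf(
      "depth %d exceeds library size of sample(s): %s", depth,
      paste(sprintf("%s (%d)", names(sums)[low], sums[low]), collapse = ", ")))
  }
  # rrarefy's small-count heuristic warning is noise for toy tables; the
  # subsampling semantics are asserted by the test suite
  rarefied <- withr::with_seed(as.integer(seed),
    suppressWarnings(t(vegan::rrarefy(t(table$counts), depth))))
  dimnames(rarefied) <- dimnames(table$counts)
  asv_table(rarefied, table$metadata)
}

#' Filter taxa by within-group prevalence
#'
#' Restricts the table to one group's samples and keeps only taxa detected
#' (count > 0) in at least `ceiling(min_fraction * n_group_samples)` of
#' them — with the default 0.5 this is the "present in at least half of the
#' samples within each group" rule used before co-occurrence analysis.
#'
#' @param table An [asv_table()].
#' @param group Group label to restrict to.
#' @param min_fraction Minimum fraction of the group's samples a taxon must
#'   occur in (0 < `min_fraction` <= 1, default 0.5).
#' @return An [asv_table()] containing only the group's samples and the
#'   taxa passing the prevalence threshold.
#' @export
filter_prevalence <- function(table, group, min_fraction = 0.5) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    abort_invalid("`min_fraction` must lie in (0, 1]")
  }
  samples <- group_samples(table, group)
  sub <- table$counts[, samples, drop = FALSE]
  need <- ceiling(min_fraction * length(samples))
  keep <- rowSums(sub > 0) >= need
  asv_table(sub[keep, , drop = FALSE],
            table$metadata[table$metadata$sample_id %in% samples, ])
}

#' Aggregate taxa to a higher rank
#'
#' Sums counts of taxa sharing a label (typically phylum); taxa missing
#' from the map are pooled into `"unclassified"`. Per-sample totals are
#' conserved.
#'
#' @param table An [asv_table()].
#' @param taxonomy Data frame with columns `taxon_id` and `phylum` (or any
#'   label column named by `rank`).
#' @param rank Name of the label column in `taxonomy`. Default `"phylum"`.
#' @return An [asv_table()] with one row per label.
#' @export
aggregate_taxa <- function(table, taxonomy, rank = "phylum") {
  if (!all(c("taxon_id", rank) %in% names(taxonomy))) {
    abort_invalid(sprintf("`taxonomy` needs columns `taxon_id` and `%s`", rank))
  }
  labels <- taxonomy[[rank]][match(taxa_names(table), taxonomy$taxon_id)]
  labels[is.na(labels)] <- "unclassified"
  agg <- rowsum(table$counts, group = labels)
  asv_table(agg[order(rownames(agg)), , drop = FALSE], table$metadata)
}

#' Convert counts to relative abundances
#'
#' @param table An [asv_table()] or a taxa-by-samples count matrix.
#' @return A numeric matrix of the same shape whose columns each sum to 1.
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "asv_table")) table$counts else table
  sums <- colSums(m)
  if (any(sums == 0)) {
    abort_invalid(sprintf("zero-sum sample(s): %s",
                          paste(colnames(m)[sums == 0], collapse = ", ")))
  }
  sweep(m, 2, sums, "/")
}
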