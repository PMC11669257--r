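#' Per-feature Wilcoxon rank-sum tests with BH correction
#'
#' Compares each feature (row) between two groups with the two-sided
#' Wilcoxon rank-sum test, then applies the Benjamini-Hochberg step-up
#' adjustment across all tested features. The exact null distribution is
#' used for small tie-free samples and the normal approximation with
#' continuity correction otherwise (the [stats::wilcox.test()] defaults).
#' Features constant across all samples carry no rank information; they are
#' recorded with `p_value = 1` and flagged.
#'
#' @param features A features-by-samples numeric matrix (e.g. phylum
#'   relative abundances) or an [asv_table()].
#' @param groups Group label per sample (named vector or metadata tibble
#'   with `sample_id`/`group`).
#' @param group_a,group_b The two group labels to compare.
#' @return A tibble with columns `feature`, `statistic`, `p_value`,
#'   `p_adjusted`, `constant`.
#' @export
wilcoxon_bh <- function(features, groups, group_a, group_b) {
  m <- if (inherits(features, "asv_table")) {
    if (is.null(groups)) groups <- features$metadata
    features$counts
  } else {
    as.matrix(features)
  }
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$sample_id)
  if (!is.null(names(groups))) groups <- groups[colnames(m)]
  a <- which(groups == group_a)
  b <- which(groups == group_b)
  if (length(a) < 2 || length(b) < 2) {
    abort_invalid("each group needs at least 2 samples")
  }
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    xa <- m[i, a]; xb <- m[i, b]
    if (length(unique(c(xa, xb))) == 1L) {
      return(list(statistic = NA_real_, p_value = 1, constant = TRUE))
    }
    ht <- suppressWarnings(wilcox.test(xa, xb, alternative = "two.sided"))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         constant = FALSE)
  })
  out <- tibble::tibble(
    feature = rownames(m) %||% as.character(seq_len(nrow(m))),
    statistic = purrr::map_dbl(res, "statistic"),
    p_value = purrr::map_dbl(res, "p_value"),
    constant = purrr::map_lgl(res, "constant"))
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  dplyr::relocate(out, "constant", .after = "p_adjusted")
}

# Compact letter display: groups joined by an edge when their pairwise
# comparison is non-significant; one letter per maximal clique of that
# graph, so two groups share a letter iff they are mutually non-distinct.
compact_letters <- function(group_names, ns_pairs) {
  g <- igraph::make_empty_graph(n = length(group_names), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = group_names)
  if (nrow(ns_pairs)) {
    g <- igraph::add_edges(g, t(as.matrix(ns_pairs)))
  }
  cliques <- igraph::max_cliques(g)
  cliques <- cliques[order(-vapply(cliques, length, integer(1)))]
  letters_of <- setNames(rep("", length(group_names)), group_names)
  for (i in seq_along(cliques)) {
    members <- igraph::V(g)$name[as.integer(cliques[[i]])]
    letters_of[members] <- paste0(letters_of[members], letters[i])
  }
  vapply(letters_of, function(s) paste(sort(strsplit(s, "")[[1]]),
                                       collapse = ""), character(1))
}

#' One-way ANOVA with Tukey HSD and compact letters
#'
#' Standard one-way ANOVA followed by Tukey's honest significant difference
#' test for all pairwise group contrasts, with a compact letter display
#' (groups that are not significantly different share a letter). An
#' optional log10 transformation normalizes right-skewed network metrics;
#' zeros are offset by half the smallest positive value, and the offset is
#' recorded in the result.
#'
#' @param values Numeric response vector.
#' @param groups Group label per value (>= 2 groups, each with >= 2
#'   values).
#' @param log10_transform Apply `log10` before testing? Default `FALSE`.
#' @param alpha Significance level for the letter display. Default 0.05.
#' @return A list of class `anova_tukey` with `F_value`, `df`, `p_value`,
#'   `tukey` (tibble: `contrast`, `estimate`, `conf_low`, `conf_high`,
#'   `p_adjusted`), `letters` (tibble: `group`, `mean`, `letters`), and
#'   `zero_offset` (the applied offset, 0 if none).
#' @export
anova_tukey <- function(values, groups, log10_transform = FALSE,
                        alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort_invalid("need at least 2 groups")
  if (any(table(groups) < 2)) {
    abort_invalid("every group needs at least 2 values")
  }
  offset <- 0
  if (log10_transform) {
    if (any(values < 0)) abort_invalid("log10 transform needs values >= 0")
    if (any(values == 0)) {
      pos <- values[values > 0]
      if (!length(pos)) abort_invalid("all values are zero")
      offset <- min(pos) / 2
    }
    values <- log10(values + offset)
  }
  if (all(tapply(values, groups, function(v) length(unique(v)) == 1L))) {
    abort_invalid("zero within-group variance in every group; ANOVA is degenerate")
  }
  fit <- aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$groups
  tukey <- tibble::tibble(contrast = rownames(tk),
                          estimate = tk[, "diff"],
                          conf_low = tk[, "lwr"],
                          conf_high = tk[, "upr"],
                          p_adjusted = tk[, "p adj"])
  ns <- do.call(rbind, strsplit(tukey$contrast[tukey$p_adjusted > alpha], "-",
                                fixed = TRUE))
  if (is.null(ns)) ns <- matrix(character(0), ncol = 2)
  means <- sort(tapply(values, groups, mean), decreasing = TRUE)
  cld <- compact_letters(names(means), as.data.frame(ns))
  structure(list(F_value = an[["F value"]][1],
                 df = c(an[["Df"]][1], an[["Df"]][2]),
                 p_value = an[["Pr(>F)"]][1],
                 tukey = tukey,
                 letters = tibble::tibble(group = names(means),
                                          mean = as.numeric(means),
                                          letters = unname(cld[names(means)])),
                 zero_offset = offset),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d,%d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F_value, x$p_value))
  print(x$letters)
  invisible(x)
}

#' @rdname anova_tukey
#' @param x An `anova_tukey` result.
#' @param ... Unused.
#' @export
tidy.anova_tukey <- function(x, ...) x$tukey

#' @rdname anova_tukey
#' @export
glance.anova_tukey <- function(x, ...) {
  tibble::tibble(F_value = x$F_value, df_between = x$df[1],
                 df_within = x$df[2], p_value = x$p_value,
                 zero_offset = x$zero_offset)
}
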