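#' Beta mean nearest taxon distance
#'
#' For a pair of communities j and k, the abundance-weighted mean
#' phylogenetic distance from each taxon in one community to its nearest
#' relative in the other:
#' \deqn{\beta MNTD_{jk} = \tfrac{1}{2}\left[\sum_{i \in j} f_{ij}
#'   \min_{i' \in k} d_{ii'} + \sum_{i \in k} f_{ik}
#'   \min_{i' \in j} d_{ii'}\right]}
#' with \eqn{d} the patristic distance and \eqn{f} relative abundances
#' (or `1/richness` when `abundance_weighted = FALSE`). A taxon shared by
#' both communities has nearest-taxon distance zero.
#'
#' @param table An [asv_table()] (or taxa-by-samples matrix) whose taxa are
#'   tips of `tree`.
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @param abundance_weighted Weight by relative abundance? Default `TRUE`.
#' @return A symmetric [stats::dist] over samples.
#' @export
bmntd <- function(table, tree, abundance_weighted = TRUE) {
  m <- if (inherits(table, "asv_table")) table$counts else as.matrix(table)
  if (any(colSums(m) == 0)) {
    abort_invalid(sprintf("empty sample(s): %s",
                          paste(colnames(m)[colSums(m) == 0], collapse = ", ")))
  }
  missing <- setdiff(rownames(m), tree$tip.label)
  if (length(missing)) {
    abort_invalid(sprintf("taxa absent from the tree: %s",
                          paste(head(missing, 5), collapse = ", ")))
  }
  D <- ape::cophenetic.phylo(tree)[rownames(m), rownames(m)]
  stats::as.dist(bmntd_from_dist(m, D, abundance_weighted))
}

# Core computation on an explicit taxon distance matrix, shared by the
# observed statistic and the null replicates (which only permute D).
# M[i, k] = min distance from taxon i to any taxon present in sample k;
# betaMNTD = (A + t(A)) / 2 with A = t(F) %*% M.
bmntd_from_dist <- function(m, D, abundance_weighted) {
  pres <- m > 0
  f <- if (abundance_weighted) {
    sweep(m, 2, colSums(m), "/")
  } else {
    sweep(pres * 1, 2, colSums(pres), "/")
  }
  M <- vapply(seq_len(ncol(m)), function(k) {
    cols <- which(pres[, k])
    do.call(pmin, c(as.data.frame(D[, cols, drop = FALSE]), na.rm = FALSE))
  }, numeric(nrow(m)))
  A <- crossprod(f, M)
  out <- (A + t(A)) / 2
  dimnames(out) <- list(colnames(m), colnames(m))
  out
}

#' Beta nearest taxon index
#'
#' Standardizes the observed between-sample [bmntd()] against a null
#' distribution obtained by shuffling taxon labels across the tips of the
#' phylogeny (the "taxa.labels" null): for each sample pair,
#' \eqn{\beta NTI = (\beta MNTD_{obs} - \bar{\beta MNTD}_{null}) /
#' sd(\beta MNTD_{null})}. Values below -2 indicate homogeneous selection,
#' above +2 heterogeneous selection, and |betaNTI| < 2 stochastic
#' assembly.
#'
#' @inheritParams bmntd
#' @param n_null Number of tip-shuffling null replicates (>= 99).
#'   Default 999.
#' @param seed Integer seed for the shuffles.
#' @param comparisons Which sample pairs enter the classification
#'   fractions: `"all"`, or `"within"` for within-group pairs only
#'   (requires `table` to be an [asv_table()] with group metadata).
#' @param bnti_cut Threshold on |betaNTI| separating stochastic from
#'   deterministic assembly (strict inequalities). Default 2.
#' @return A list of class `bnti_result` with `pairs` (tibble: `sample_1`,
#'   `sample_2`, `group_1`, `group_2`, `bmntd_obs`, `null_mean`,
#'   `null_sd`, `bnti`, `label`), `fractions` (named: stochastic,
#'   homogeneous_selection, heterogeneous_selection), `n_null`, and the
#'   full `bnti` matrix.
#' @export
bnti <- function(table, tree, n_null = 999, seed = 1L,
                 abundance_weighted = TRUE, comparisons = c("all", "within"),
                 bnti_cut = 2) {
  comparisons <- match.arg(comparisons)
  m <- if (inherits(table, "asv_table")) table$counts else as.matrix(table)
  if (ncol(m) < 2) abort_invalid("need at least 2 samples")
  if (n_null < 99) abort_invalid("`n_null` must be >= 99")
  missing <- setdiff(rownames(m), tree$tip.label)
  if (length(missing)) {
    abort_invalid(sprintf("taxa absent from the tree: %s",
                          paste(head(missing, 5), collapse = ", ")))
  }
  D <- ape::cophenetic.phylo(tree)[rownames(m), rownames(m)]
  obs <- bmntd_from_dist(m, D, abundance_weighted)

  n_taxa <- nrow(m)
  sum1 <- matrix(0, ncol(m), ncol(m))
  sum2 <- matrix(0, ncol(m), ncol(m))
  perms <- withr::with_seed(as.integer(seed),
    replicate(n_null, sample.int(n_taxa), simplify = FALSE))
  for (p in perms) {
    nullv <- bmntd_from_dist(m, D[p, p, drop = FALSE], abundance_weighted)
    sum1 <- sum1 + nullv
    sum2 <- sum2 + nullv^2
  }
  null_mean <- sum1 / n_null
  null_sd <- sqrt(pmax(sum2 / n_null - null_mean^2, 0) * n_null / (n_null - 1))

  z <- (obs - null_mean) / null_sd
  diag(z) <- 0

  pair_idx <- which(upper.tri(obs), arr.ind = TRUE)
  groups <- if (inherits(table, "asv_table")) {
    setNames(table$metadata$group, table$metadata$sample_id)
  } else {
    setNames(rep(NA_character_, ncol(m)), colnames(m))
  }
  pairs <- tibble::tibble(
    sample_1 = colnames(m)[pair_idx[, 1]],
    sample_2 = colnames(m)[pair_idx[, 2]],
    group_1 = unname(groups[colnames(m)[pair_idx[, 1]]]),
    group_2 = unname(groups[colnames(m)[pair_idx[, 2]]]),
    bmntd_obs = obs[pair_idx],
    null_mean = null_mean[pair_idx],
    null_sd = null_sd[pair_idx],
    bnti = z[pair_idx])
  undefined <- pairs$null_sd == 0
  if (any(undefined)) {
    rlang::warn(sprintf(
      "%d sample pair(s) have zero null standard deviation; betaNTI undefined and excluded",
      sum(undefined)))
    pairs$bnti[undefined] <- NA_real_
  }
  pairs$label <- bnti_label(pairs$bnti, bnti_cut)

  scope <- if (comparisons == "within") {
    !is.na(pairs$group_1) & pairs$group_1 == pairs$group_2
  } else {
    rep(TRUE, nrow(pairs))
  }
  classifiable <- pairs$bnti[scope & !is.na(pairs$bnti)]
  fractions <- if (length(classifiable)) {
    classify_assembly(classifiable, bnti_cut)$fractions
  } else {
    c(stochastic = NA_real_, homogeneous_selection = NA_real_,
      heterogeneous_selection = NA_real_, deterministic = NA_real_)
  }
  structure(list(pairs = pairs, fractions = fractions, n_null = n_null,
                 comparisons = comparisons, bnti = z),
            class = "bnti_result")
}

bnti_label <- function(values, bnti_cut = 2) {
  dplyr::case_when(
    is.na(values) ~ NA_character_,
    values < -bnti_cut ~ "homogeneous_selection",
    values > bnti_cut ~ "heterogeneous_selection",
    TRUE ~ "stochastic")
}

#' Classify assembly processes from betaNTI values
#'
#' Applies the strict +/-2 thresholds: betaNTI < -2 is homogeneous
#' selection, betaNTI > 2 heterogeneous selection, and everything else
#' (including the boundaries) stochastic.
#'
#' @param values Finite betaNTI values.
#' @param bnti_cut Threshold on |betaNTI|; strict inequalities. Default 2.
#' @return A list with `labels` (tibble: `bnti`, `label`) and `fractions`
#'   (named numeric over the three processes, plus `deterministic` =
#'   homogeneous + heterogeneous; fractions sum to 1 over labelled pairs).
#' @export
classify_assembly <- function(values, bnti_cut = 2) {
  values <- values[!is.na(values)]
  if (!length(values)) abort_invalid("no finite betaNTI values to classify")
  label <- bnti_label(values, bnti_cut)
  fractions <- c(
    stochastic = mean(label == "stochastic"),
    homogeneous_selection = mean(label == "homogeneous_selection"),
    heterogeneous_selection = mean(label == "heterogeneous_selection"))
  fractions["deterministic"] <- fractions[["homogeneous_selection"]] +
    fractions[["heterogeneous_selection"]]
  list(labels = tibble::tibble(bnti = values, label = label),
       fractions = fractions)
}

#' Per-group betaNTI summary
#'
#' @param x A `bnti_result`.
#' @return A tibble with one row per group of within-group pairs:
#'   `group`, `n_pairs`, `mean_bnti`, `stochastic`,
#'   `homogeneous_selection`, `heterogeneous_selection`, `deterministic`.
#' @export
bnti_group_summary <- function(x) {
  stopifnot(inherits(x, "bnti_result"))
  within <- dplyr::filter(x$pairs, !is.na(.data$group_1),
                          .data$group_1 == .data$group_2,
                          !is.na(.data$bnti))
  dplyr::summarise(
    dplyr::group_by(within, group = .data$group_1),
    n_pairs = dplyr::n(),
    mean_bnti = mean(.data$bnti),
    stochastic = mean(.data$label == "stochastic"),
    homogeneous_selection = mean(.data$label == "homogeneous_selection"),
    heterogeneous_selection = mean(.data$label == "heterogeneous_selection"),
    deterministic = 1 - mean(.data$label == "stochastic"),
    .groups = "drop")
}

#' @export
print.bnti_result <- function(x, ...) {
  cat(sprintf("<bnti_result> %d sample pairs, %d null replicates (%s pairs classified)\n",
              nrow(x$pairs), x$n_null, x$comparisons))
  f <- x$fractions
  cat(sprintf("stochastic %.1f%% | homogeneous %.1f%% | heterogeneous %.1f%%\n",
              100 * f[["stochastic"]], 100 * f[["homogeneous_selection"]],
              100 * f[["heterogeneous_selection"]]))
  invisible(x)
}

#' @rdname bnti
#' @param x A `bnti_result`.
#' @param ... Unused.
#' @export
tidy.bnti_result <- function(x, ...) x$pairs

#' @rdname bnti
#' @export
glance.bnti_result <- function(x, ...) {
  tibble::tibble(n_pairs = sum(!is.na(x$pairs$bnti)), n_null = x$n_null,
                 stochastic = x$fractions[["stochastic"]],
                 homogeneous_selection = x$fractions[["homogeneous_selection"]],
                 heterogeneous_selection = x$fractions[["heterogeneous_selection"]],
                 deterministic = x$fractions[["deterministic"]])
}
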