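#' Permutational multivariate analysis of variance
#'
#' Tests whether community composition differs between groups by
#' partitioning squared distances (Anderson's pseudo-F) and permuting
#' sample labels freely; the p-value is
#' `(number of permuted F >= observed F + 1) / (n_permutations + 1)`.
#' Computation is delegated to [vegan::adonis2()] under a fixed seed.
#'
#' @param dm Distance matrix ([stats::dist] or symmetric matrix) over
#'   samples.
#' @param groups Group label per sample, either a vector in distance-matrix
#'   order, a named vector, or a metadata tibble with `sample_id`/`group`.
#' @param n_permutations Number of label permutations. Default 999.
#' @param seed Integer seed making the permutation p-value reproducible.
#' @return A list of class `permanova_result` with `pseudo_F`, `R2`,
#'   `p_value`, `df_between`, `df_within`, `n_permutations`.
#' @export
permanova <- function(dm, groups, n_permutations = 999, seed = 1L) {
  m <- as.matrix(dm)
  ids <- rownames(m)
  if (is.data.frame(groups)) {
    groups <- setNames(groups$group, groups$sample_id)
  }
  if (!is.null(names(groups)) && !is.null(ids)) {
    groups <- groups[ids]
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort_invalid("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    abort_invalid(sprintf("group(s) with fewer than 2 samples: %s",
                          paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  df <- data.frame(group = groups)
  fit <- withr::with_seed(as.integer(seed),
    vegan::adonis2(stats::as.dist(m) ~ group, data = df,
                   permutations = n_permutations))
  structure(list(pseudo_F = fit$F[1],
                 R2 = fit$R2[1],
                 p_value = fit$`Pr(>F)`[1],
                 df_between = fit$Df[1],
                 df_within = fit$Df[2],
                 n_permutations = n_permutations),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d,%d) = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$df_between, x$df_within, x$pseudo_F, x$R2, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' @rdname permanova
#' @param x A `permanova_result`.
#' @param ... Unused.
#' @export
tidy.permanova_result <- function(x, ...) {
  tibble::tibble(term = "group", df = x$df_between, pseudo_F = x$pseudo_F,
                 R2 = x$R2, p_value = x$p_value)
}

#' @rdname permanova
#' @export
glance.permanova_result <- function(x, ...) {
  tibble::tibble(pseudo_F = x$pseudo_F, R2 = x$R2, p_value = x$p_value,
                 df_between = x$df_between, df_within = x$df_within,
                 n_permutations = x$n_permutations)
}
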