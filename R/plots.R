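# ggplot2 views of the main result types. All plots are optional sugar;
# the analysis surface is the tables.

#' @export
autoplot.pcoa_ordination <- function(object, ...) {
  coords <- object$coordinates
  pct <- function(i) {
    if (length(object$prop_explained) >= i) {
      sprintf(" (%.1f%%)", 100 * object$prop_explained[i])
    } else ""
  }
  p <- ggplot2::ggplot(coords, ggplot2::aes(.data$Axis.1, .data$Axis.2)) +
    ggplot2::labs(x = paste0("PCoA 1", pct(1)), y = paste0("PCoA 2", pct(2)))
  if ("group" %in% names(coords)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$group,
                                              shape = .data$group), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::theme_minimal()
}

#' @export
autoplot.bnti_result <- function(object, ...) {
  within <- dplyr::filter(object$pairs, !is.na(.data$group_1),
                          .data$group_1 == .data$group_2,
                          !is.na(.data$bnti))
  ggplot2::ggplot(within, ggplot2::aes(.data$group_1, .data$bnti,
                                       fill = .data$group_1)) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(beta * "NTI")) +
    ggplot2::theme_minimal()
}

#' Zi-Pi role plot
#'
#' Scatter of within-module connectivity against participation with the
#' role-threshold lines.
#'
#' @param roles Role tibble from [zi_pi()] (a `group` column is mapped to
#'   colour when present).
#' @param zi_cut,pi_cut Thresholds to draw. Defaults 2.5 and 0.62.
#' @return A ggplot object.
#' @export
plot_zi_pi <- function(roles, zi_cut = 2.5, pi_cut = 0.62) {
  p <- ggplot2::ggplot(roles, ggplot2::aes(.data$pi, .data$zi))
  if ("group" %in% names(roles)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$group,
                                              shape = .data$role))
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(shape = .data$role))
  }
  p + ggplot2::geom_hline(yintercept = zi_cut, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = pi_cut, linetype = "dashed") +
    ggplot2::labs(x = "Among-module connectivity (Pi)",
                  y = "Within-module connectivity (Zi)") +
    ggplot2::theme_minimal()
}

#' Robustness replicate plot
#'
#' Mean +/- standard error of the replicate robustness per group.
#'
#' @param replicates A tibble with columns `group` and `robustness` (e.g.
#'   robustness tibbles row-bound with a `group` column).
#' @return A ggplot object.
#' @export
plot_robustness <- function(replicates) {
  summary <- dplyr::summarise(
    dplyr::group_by(replicates, .data$group),
    mean = mean(.data$robustness),
    se = sd(.data$robustness) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(summary, ggplot2::aes(.data$group, .data$mean,
                                        fill = .data$group)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "Robustness (fraction of taxa remaining)") +
    ggplot2::theme_minimal()
}
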