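# ggplot2 views of the main result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Consensus-matrix heatmap
#'
#' @param result A `subtyping_result`.
#' @param k Rank to display (default: the selected rank).
#' @return A ggplot object.
#' @export
plot_consensus <- function(result, k = NULL) {
  stopifnot(inherits(result, "subtyping_result"))
  k <- k %||% result$k_selected
  cm <- result$per_k[[as.character(k)]]$consensus
  ord <- stats::hclust(as.dist(1 - cm), method = "average")$order
  df <- tibble::as_tibble(cm[ord, ord], rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b", values_to = "consensus")
  df$sample_a <- factor(df$sample_a, levels = rownames(cm)[ord])
  df$sample_b <- factor(df$sample_b, levels = rownames(cm)[ord])
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "co-clustering",
                  title = sprintf("Consensus matrix (k = %d)", k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Cophenetic coefficient profile across ranks
#'
#' @param object A `subtyping_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot subtyping_result
#' @export
autoplot.subtyping_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$cophenetic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$selected), size = 3) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey30"),
                                guide = "none") +
    ggplot2::labs(x = "rank k", y = "cophenetic coefficient",
                  title = "Rank selection: value before the steepest fall") +
    ggplot2::theme_minimal()
}

#' FPR/TPR sweep curves of a panel classifier
#'
#' @param object A `panel_classifier`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot panel_classifier
#' @export
autoplot.panel_classifier <- function(object, ...) {
  df <- tidyr::pivot_longer(object$sweep, c("fpr", "tpr"),
                            names_to = "rate", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$n, .data$value, color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$selected_n, linetype = 2) +
    ggplot2::facet_wrap(~rate, ncol = 1) +
    ggplot2::labs(x = "panel size n", y = NULL,
                  title = sprintf("Panel sweep (selected n = %d)", object$selected_n)) +
    ggplot2::theme_minimal()
}

#' Module-trait correlation heatmap
#'
#' @param object A completed `module_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot module_result
#' @export
autoplot.module_result <- function(object, ...) {
  if (is.null(object$module_trait)) {
    stop("run module_trait_stats() first", call. = FALSE)
  }
  ggplot2::ggplot(object$module_trait,
                  ggplot2::aes(.data$trait, factor(.data$module),
                               fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = "cell type", y = "module", fill = "r",
                  title = "Module-trait correlations") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step curves
#'
#' @param km Tidy curve tibble from [km_estimate()].
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  ggplot2::ggplot(km, ggplot2::aes(.data$time, .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Dot plot of ligand-receptor interactions
#'
#' @param interactions Result of [permutation_test()].
#' @param max_p Display only combinations with p at or below this value.
#' @return A ggplot object.
#' @export
plot_interactions <- function(interactions, max_p = 1) {
  df <- interactions[!is.na(interactions$p) & interactions$p <= max_p, ]
  df$pair_types <- paste(df$type_a, df$type_b, sep = " → ")
  ggplot2::ggplot(df, ggplot2::aes(.data$pair_types, .data$pair_id,
                                   size = -log10(.data$p),
                                   color = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_gradient(low = "grey70", high = "firebrick") +
    ggplot2::labs(x = "sender → receiver", y = "ligand-receptor pair",
                  size = "-log10 p", color = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
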