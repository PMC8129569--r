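#' Heatmap of an aggregated gene clustering
#'
#' Standardized expression of the clustered genes, rows ordered by
#' aggregated cluster — a diagnostic analogue of the annotated signature
#' heatmaps.
#'
#' @param object An `agg_state`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot agg_state
#' @export
autoplot.agg_state <- function(object, ...) {
  ord <- names(sort(object$assignment))
  long <- matrix_to_expr(object$data) |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "z") |>
    dplyr::mutate(gene_id = factor(.data$gene_id, levels = ord),
                  cluster = object$assignment[as.character(.data$gene_id)])
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$gene_id,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-score",
                  title = "Genes by aggregated cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Top-clone frequency bars per repertoire library
#'
#' One panel per sample and chain, membrane and secreted libraries side by
#' side; the dominant clone of each library is drawn first.
#'
#' @param report A `clone_report` from [top_clone_frequencies()].
#' @return A ggplot object.
#' @export
plot_clone_frequencies <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(factor(.data$rank), .data$frequency,
                               fill = .data$isoform)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chain),
                        cols = ggplot2::vars(.data$sample_id)) +
    ggplot2::labs(x = "clone rank", y = "relative frequency",
                  title = "Most abundant clones per library") +
    ggplot2::theme_minimal()
}

#' Posterior probabilities of LPS predictions
#'
#' Samples ordered by linear predictor score, colored by three-way call,
#' with the call thresholds drawn.
#'
#' @param predictions Tibble from [predict.lps_model()].
#' @param model The `lps_model` used (for its thresholds).
#' @return A ggplot object.
#' @export
plot_lps_predictions <- function(predictions, model) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(stats::reorder(.data$sample_id, .data$lps),
                               .data$posterior, color = .data$call)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(model$p_lo, model$p_hi),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "posterior P(positive class)",
                  title = "LPS classifier calls") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
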