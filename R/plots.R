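# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot evaluation results
#'
#' Bar chart of per-protein recall, precision and F-value.
#'
#' @param object A `pl_eval` from [evaluate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pl_eval <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_protein,
                           cols = c("recall", "precision", "f_value"),
                           names_to = "metric", values_to = "value")
  d$metric <- factor(d$metric, levels = c("recall", "precision", "f_value"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$protein, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "score", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a co-occurrence Z-score distribution
#'
#' Histogram of pair Z-scores with the conventional 95% normal bounds; on
#' an independent corpus the distribution should be close to standard
#' normal.
#'
#' @param stats A tibble from [cooccurrence_stats()] (or a
#'   `pl_pair_index`).
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_zscores <- function(stats, bins = 50) {
  d <- tibble::as_tibble(stats)
  d <- d[!is.na(d$z), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey65", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(-1.96, 1.96), linetype = "dashed") +
    ggplot2::labs(x = "pair Z-score", y = "pairs") +
    ggplot2::theme_minimal()
}

#' Plot prediction records
#'
#' Support counts per predicted category, split by evidence type.
#'
#' @param object A `pl_predictions` from [annotate_protein()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pl_predictions <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$category, .data$support),
                                  y = .data$support, fill = .data$evidence)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "supporting evidence items", fill = "evidence") +
    ggplot2::theme_minimal()
}
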