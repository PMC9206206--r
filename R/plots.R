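#' Plot a pretest probability table
#'
#' Estimated probability that the next result is normal against the number
#' of immediately preceding consecutive normal results, with point size
#' showing the supporting event count.
#'
#' @param object A `pretest_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pretest_table <- function(object, ...) {
  p <- ggplot(object, aes(x = M, y = probability)) +
    geom_line(colour = "grey40") +
    geom_point(aes(size = n_total), alpha = 0.8) +
    scale_size_area(name = "events") +
    labs(x = "consecutive prior normal results (M)",
         y = "P(next result normal | M)",
         title = "Pretest probability of a normal result") +
    ylim(0, 1) +
    theme_minimal()
  if ("test_type" %in% names(object)) {
    p <- p + facet_wrap(~test_type)
  }
  p
}

#' Plot fold-level metric distributions of an experiment
#'
#' Boxplots of the per-fold metric values by approach and classifier — the
#' experiment-level view of how the feature approaches compare on each
#' metric.
#'
#' @param object An `icu_experiment`.
#' @param metrics Metrics to show (default: all 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.icu_experiment <- function(object, metrics = metric_names(), ...) {
  long <- object$metrics |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(metric = factor(metric, levels = metrics))
  ggplot(long, aes(x = classifier, y = .data$value, fill = approach)) +
    geom_boxplot(outlier.size = 0.5, linewidth = 0.3) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = "fold-level value",
         title = "Cross-validated performance by approach") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}

#' Plot percent change between approaches with significance marks
#'
#' Bar chart of the percent change of the 10-fold metric means of each
#' comparison approach relative to approach 1; significant comparisons
#' (Benjamini-Hochberg adjusted) are starred.
#'
#' @param report An `icu_experiment`.
#' @return A ggplot object.
#' @export
plot_percent_change <- function(report) {
  stopifnot(inherits(report, "icu_experiment"))
  d <- report$comparison |>
    dplyr::filter(!is.na(pct_change)) |>
    dplyr::mutate(label = ifelse(!is.na(significant) & significant, "*", ""))
  ggplot(d, aes(x = metric, y = pct_change, fill = classifier)) +
    geom_col(position = "dodge") +
    geom_text(aes(label = .data$label, group = classifier),
              position = position_dodge(width = 0.9), vjust = 0) +
    facet_grid(approach ~ test_type) +
    labs(x = NULL, y = "% change of fold means vs approach 1",
         title = "Approach comparison (starred = significant at the FDR)") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}
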