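# ggplot2 autoplot methods for the main result types.

#' Plot a k-selection curve
#'
#' Elbow (within-cluster sum of squares) and mean-silhouette panels over
#' the k sweep, with the selected k marked.
#'
#' @param object A `k_selection_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot k_selection_curve
#' @export
autoplot.k_selection_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve, c("wcss", "silhouette"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = c("wcss", "silhouette"),
                        labels = c("within-cluster SS (elbow)",
                                   "mean silhouette"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "number of clusters k", y = NULL,
                  title = sprintf("Cluster-count selection (selected k = %d)",
                                  object$selected_k)) +
    ggplot2::theme_minimal()
}

#' Plot a paired emotion-change summary
#'
#' Per-emotion Cohen's d with its confidence interval, signed by the
#' direction of change (negative = lower in phase 2).
#'
#' @param object A `paired_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot paired_summary
#' @export
autoplot.paired_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  sgn <- sign(df$mean_diff)
  df$d_signed <- sgn * df$d
  df$lo <- sgn * ifelse(sgn >= 0, df$d_low, df$d_high)
  df$hi <- sgn * ifelse(sgn >= 0, df$d_high, df$d_low)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$emotion, .data$d_signed),
                                   y = .data$d_signed)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "signed Cohen's d (phase 2 - phase 1)",
                  title = "Emotion change between phases") +
    ggplot2::theme_minimal()
}

#' Plot a cluster profile
#'
#' Mean change per emotion and cluster, with SD error bars.
#'
#' @param object A `cluster_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_profile
#' @export
autoplot.cluster_profile <- function(object, ...) {
  df <- object$emotions
  df$cluster <- factor(df$cluster)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$emotion, y = .data$mean_change,
                                   fill = .data$cluster)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_change - .data$sd_change,
                   ymax = .data$mean_change + .data$sd_change),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "mean change (phase 2 - phase 1)",
                  title = "Emotion-change profiles by cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an n-gram shift table
#'
#' Diverging bars of mean r for the top increased and decreased n-grams,
#' with the across-iteration spread as error bars.
#'
#' @param object A `shift_table`.
#' @param n Entries per direction (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shift_table
#' @export
autoplot.shift_table <- function(object, n = 15, ...) {
  df <- dplyr::bind_rows(utils::head(object$increased, n),
                         utils::head(object$decreased, n))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$ngram, .data$mean_r),
                                   y = .data$mean_r,
                                   fill = .data$mean_r > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_r - .data$spread,
                                        ymax = .data$mean_r + .data$spread),
                           width = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean rank-biserial r (phase 2 vs phase 1)",
                  title = "Most shifted n-grams") +
    ggplot2::theme_minimal()
}
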