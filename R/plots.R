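# ggplot2 views of the three result types: diverging score bars, coefficient
# dot-and-whisker, and the preference-vs-budget grouped bars.

#' Plot mean best-worst scores
#'
#' Horizontal diverging bars of per-item mean best-worst scores, ordered by
#' rank, with +/- 1.96 SE whiskers where standard errors are available.
#'
#' @param object A `bws_counts` tibble from [bw_scores()] or
#'   [bw_scores_from_counts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bws_counts <- function(object, ...) {
  df <- dplyr::mutate(object,
                      item = stats::reorder(.data$item_id, .data$score))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$item)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$score > 0), show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "mean best-worst score", y = NULL)
  if (!all(is.na(df$se))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$score - 1.96 * .data$se,
                   xmax = .data$score + 1.96 * .data$se),
      height = 0.25
    )
  }
  p
}

#' Plot fitted utilities of a sequential best-worst logit
#'
#' Dot-and-whisker plot of the recovered per-item utilities with 95%
#' confidence intervals, ordered by rank; the omitted (recovered) level is
#' marked.
#'
#' @param object A `bws_clogit` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bws_clogit <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(item = stats::reorder(.data$term, .data$estimate))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$item)) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3, linetype = 2) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$omitted), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                labels = c("estimated", "recovered"),
                                name = NULL) +
    ggplot2::labs(x = "utility estimate (95% CI)", y = NULL)
}

#' Plot preference shares against budget shares
#'
#' Grouped horizontal bars comparing each item's percentage preference share
#' with its percentage budget allocation, ordered by preference rank.
#'
#' @param object A `bws_budget_comparison` from [compare_with_budget()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bws_budget_comparison <- function(object, ...) {
  df <- object |>
    tidyr::pivot_longer(c("pref_share_pct", "budget_share_pct"),
                        names_to = "source", values_to = "pct") |>
    dplyr::mutate(
      source = dplyr::recode(.data$source,
                             pref_share_pct = "stated preference",
                             budget_share_pct = "budget allocation"),
      item = stats::reorder(.data$item_id, -.data$pref_rank)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct, y = .data$item,
                                   fill = .data$source)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::labs(x = "share of total (%)", y = NULL, fill = NULL)
}
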