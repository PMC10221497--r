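#' Three-panel counterfactual impact plot from a per-date effect table
#'
#' Panels: observed vs counterfactual with its credible ribbon, pointwise
#' effect, and cumulative effect. Accepts the per-date table produced by
#' [estimate_impact()] (or read back from its CSV), so a report can be
#' drawn from serialized stage output without recomputation.
#'
#' @param series A data frame with columns `date`, `observed`, `predicted`,
#'   `lower`, `upper`, `point_effect`, `cum_effect`.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_impact_series <- function(series, title = NULL) {
  series <- as_tibble(series)
  series$date <- as.Date(series$date)
  long <- dplyr::bind_rows(
    dplyr::transmute(series, date = .data$date, panel = "original",
                     observed = .data$observed, line = .data$predicted,
                     lower = .data$lower, upper = .data$upper),
    dplyr::transmute(series, date = .data$date, panel = "pointwise",
                     observed = NA_real_, line = .data$point_effect,
                     lower = NA_real_, upper = NA_real_),
    dplyr::transmute(series, date = .data$date, panel = "cumulative",
                     observed = NA_real_, line = .data$cum_effect,
                     lower = NA_real_, upper = NA_real_)
  ) %>%
    dplyr::mutate(panel = factor(.data$panel, c("original", "pointwise", "cumulative")))
  boundary <- min(series$date[!is.na(series$predicted)], na.rm = TRUE)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_ribbon(
      data = function(d) d[!is.na(d$lower) & !is.na(d$upper), , drop = FALSE],
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "black", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$line), colour = "steelblue",
                       linetype = "dashed", na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = boundary, linetype = "dotted") +
    ggplot2::facet_wrap(~panel, ncol = 1L, scales = "free_y") +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn estimate_impact Three-panel impact plot.
#' @method autoplot impact_result
#' @param object An `impact_result`.
#' @export
autoplot.impact_result <- function(object, ...) {
  plot_impact_series(object$series,
                     title = sprintf("Counterfactual impact (%s)", object$kind))
}

#' Dot plot of per-period trust-dimension scores
#'
#' @param scores Long-format scores (`term`, `group`, `period`, `score`),
#'   as from [tidy.trust_axis_report()].
#' @param group Optional single group to display.
#' @return A ggplot object.
#' @export
plot_trust_scores <- function(scores, group = NULL) {
  df <- as_tibble(scores)
  if (!is.null(group)) df <- df[df$group == group, , drop = FALSE]
  df <- df[!is.na(df$score), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$term,
                                   colour = .data$period)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(size = 3) +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(pre = "#3366aa", post = "#ee7722")) +
    ggplot2::labs(x = "cosine similarity to trust dimension", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn compare_periods Dot plot of per-period scores.
#' @method autoplot trust_axis_report
#' @param object A `trust_axis_report`.
#' @export
autoplot.trust_axis_report <- function(object, ...) {
  plot_trust_scores(tidy(object))
}

#' Bar chart of standardized term volumes
#'
#' @param volumes A [volume_table()] tibble (`term`, `period`, `polarity`,
#'   `zscore`).
#' @return A ggplot object.
#' @export
plot_volume <- function(volumes) {
  df <- as_tibble(volumes)
  df$period <- factor(df$period, c("pre", "post"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$zscore,
                                   fill = .data$period)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~polarity, ncol = 1L) +
    ggplot2::scale_fill_manual(values = c(pre = "#3366aa", post = "#ee7722")) +
    ggplot2::labs(x = NULL, y = "standardized volume") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn volume_table Bar chart of standardized volumes.
#' @method autoplot volume_table
#' @param object A `volume_table`.
#' @param ... Unused.
#' @export
autoplot.volume_table <- function(object, ...) {
  plot_volume(object)
}

#' Bar chart of top topic terms
#'
#' @param term_weights A tibble (`topic`, `term`, `weight`, `count`), e.g.
#'   [top_terms()] results bound with a `topic` column.
#' @return A ggplot object.
#' @export
plot_term_weights <- function(term_weights) {
  df <- as_tibble(term_weights)
  df$term <- stats::reorder(paste(df$term, df$topic), df$weight)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~topic, scales = "free_y") +
    ggplot2::scale_y_discrete(labels = function(l) sub(" [^ ]+$", "", l)) +
    ggplot2::labs(x = "topic-word weight", y = NULL) +
    ggplot2::theme_minimal()
}
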