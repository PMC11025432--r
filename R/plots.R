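#' Dot plot of onset medians within and between clusters
#'
#' One row per cluster; small points are per-disease median ages at
#' diagnosis, large points the pooled cluster medians.
#'
#' @param object An [onset_profile()] table (must contain both levels and a
#'   `cluster_id` column).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.onset_table <- function(object, ...) {
  if (!"cluster_id" %in% names(object) ||
      !all(c("cluster", "disease") %in% object$level)) {
    abort("autoplot needs an onset_profile() table with both levels")
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$median_age, y = .data$cluster_id)) +
    ggplot2::geom_point(
      data = ~ filter(.x, .data$level == "disease"),
      colour = "steelblue", alpha = 0.6, size = 1.5
    ) +
    ggplot2::geom_point(
      data = ~ filter(.x, .data$level == "cluster"),
      colour = "firebrick", size = 3.5, shape = 18
    ) +
    ggplot2::labs(x = "Median age at diagnosis (years)", y = NULL,
                  title = "Onset age within and between clusters") +
    ggplot2::theme_minimal()
}

#' Forest-style plot of adjusted odds ratios by cluster
#'
#' Per-disease point estimates (coloured by statistical significance) and
#' the cluster-level estimates, on a log odds-ratio axis.
#'
#' @param object An [odds_ratio_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.or_table <- function(object, ...) {
  usable <- filter(object, !is.na(.data$aOR))
  ggplot2::ggplot(usable,
                  ggplot2::aes(x = .data$aOR, y = .data$cluster_id)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(
      data = ~ filter(.x, .data$level == "disease"),
      ggplot2::aes(colour = .data$significant), alpha = 0.7, size = 1.5
    ) +
    ggplot2::geom_point(
      data = ~ filter(.x, .data$level == "cluster"),
      colour = "firebrick", size = 3.5, shape = 18
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "steelblue", `FALSE` = "grey70"),
      name = "significant"
    ) +
    ggplot2::labs(
      x = "Adjusted odds ratio (log scale)", y = NULL,
      title = sprintf("Odds ratios within and between clusters (%s)",
                      usable$outcome[1])
    ) +
    ggplot2::theme_minimal()
}

#' AIC comparison plot across representations
#'
#' Dot chart of AIC per representation, facetted by outcome; lower is
#' better. The disease-level reference model is highlighted.
#'
#' @param object A [compare_strategies()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.strategy_comparison <- function(object, ...) {
  tab <- as_tibble(object) |>
    mutate(is_reference = .data$representation == "diseases")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$AIC,
                                    y = stats::reorder(.data$representation,
                                                       -.data$AIC))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_reference), size = 3) +
    ggplot2::facet_wrap(~outcome, scales = "free_x") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "steelblue"), guide = "none"
    ) +
    ggplot2::labs(x = "AIC (lower is better)", y = NULL,
                  title = "Model performance by representation") +
    ggplot2::theme_minimal()
}
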