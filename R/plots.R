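#' Plot a trajectory's relative abundances over cycles
#'
#' @param object A `drift_trajectory` run with `record = "all"`.
#' @param ... Unused.
#' @return A ggplot object: per-population relative abundance against
#'   cycle, faceted by functional group when groups are present.
#' @export
autoplot.drift_trajectory <- function(object, ...) {
  df <- tidy(object)
  df <- df |>
    dplyr::group_by(.data$cycle) |>
    dplyr::mutate(relative_abundance = .data$abundance / sum(.data$abundance)) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cycle, y = .data$relative_abundance,
    group = .data$population, colour = .data$population
  )) +
    ggplot2::geom_line(show.legend = length(unique(df$population)) <= 12) +
    ggplot2::labs(x = "dilution-growth cycle", y = "relative abundance") +
    ggplot2::theme_minimal()
  if (length(unique(df$group)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$group), labeller = "label_both")
  }
  p
}

#' Plot a success profile
#'
#' @param object A `drift_success` from [success_profile()].
#' @param ... Unused.
#' @return A ggplot object: success rate against cycle with the success
#'   threshold marked.
#' @export
autoplot.drift_success <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$cycle, .data$success_rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$success_threshold,
                        linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "dilution-growth cycle", y = "success rate") +
    ggplot2::theme_minimal()
}

#' Success against dilution factor
#'
#' Summarises a scenario run: for each dilution factor, the earliest cycle
#' at which the success threshold was reached (or no success).
#'
#' @param summary The `summary` tibble returned by [run_scenario()] (or
#'   read from its `summary.tsv`).
#' @return A ggplot object.
#' @export
plot_success_vs_dilution <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = factor(.data$dilution_factor),
    y = .data$earliest_success_cycle
  )) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5) +
    ggplot2::labs(x = "dilution factor", y = "earliest success cycle") +
    ggplot2::theme_minimal()
}
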