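# ggplot2 visualisations of profiles, crossover calls, stringency reports
# and power surfaces.

#' Plot junction profiles as per-position WT / non-WT stacks
#'
#' One panel per amplicon class (library, left and right junction sites),
#' one bar per window position, split into wild-type (green) and
#' non-wild-type (purple) fractions — the standard way to eyeball where the
#' randomized bases segregate and hence where the crossover falls.
#'
#' @param object A [junction_profiles] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.junction_profiles <- function(object, ...) {
  wt <- strsplit(object$wt_window, "", fixed = TRUE)[[1]]
  df <- tidy(object) %>%
    mutate(
      status = ifelse(.data$base == wt[.data$position], "WT", "non-WT"),
      class = factor(.data$class, levels = c("library", "left", "right"))
    ) %>%
    group_by(.data$class, .data$position, .data$status) %>%
    summarise(freq = sum(.data$freq), .groups = "drop")
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = factor(.data$position), y = .data$freq,
      fill = .data$status
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~class, ncol = 1) +
    ggplot2::scale_fill_manual(values = c(`non-WT` = "#7B3294", WT = "#008837")) +
    ggplot2::labs(
      x = "window position", y = "base frequency", fill = NULL,
      title = "Segregation of randomized bases across junction sites"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the boundary log-likelihood curve of a crossover call
#'
#' @param object A `crossover_call` from [infer_boundary()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crossover_call <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$boundary, y = .data$loglik)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_max), size = 2) +
    ggplot2::geom_vline(
      xintercept = object$boundary_hat,
      linetype = "dashed", colour = "#7B3294"
    ) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#7B3294", `FALSE` = "grey30")) +
    ggplot2::scale_x_continuous(breaks = df$boundary) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(
      x = "candidate crossover boundary b", y = "log-likelihood",
      title = paste0("Crossover boundary: b = ", object$boundary_hat)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a boundary-recovery power surface
#'
#' @param object A `power_curve` tibble from [power_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_curve <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = factor(.data$depth), y = factor(.data$error_rate),
      fill = .data$recovery
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f", .data$recovery)),
      colour = "white"
    ) +
    ggplot2::scale_fill_gradient(low = "grey20", high = "#008837", limits = c(0, 1)) +
    ggplot2::labs(
      x = "depth (reads per junction site)", y = "substitution error rate",
      fill = "recovery",
      title = "Crossover boundary recovery rate"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-position stringency skew
#'
#' Bars show the relative skew of non-WT retention against the neutral
#' expectation (0 = neutral, -1 = completely purged); positions whose BH
#' q-value falls below `alpha` are marked as significantly depleted/enriched.
#'
#' @param report A tibble from [stringency_skew()].
#' @param alpha Significance threshold on the BH q-value.
#' @return A ggplot.
#' @export
plot_stringency <- function(report, alpha = 0.05) {
  df <- mutate(report, significant = !is.na(.data$q_value) & .data$q_value < alpha)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = factor(.data$position), y = .data$skew, fill = .data$significant)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#7B3294", `FALSE` = "grey60"),
      labels = c(`TRUE` = paste0("q < ", alpha), `FALSE` = "ns")
    ) +
    ggplot2::labs(
      x = "window position",
      y = "non-WT retention skew (obs - exp) / exp",
      fill = NULL,
      title = "Per-position sequence stringency after recombination"
    ) +
    ggplot2::theme_minimal()
}
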