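# ggplot2 displays for the main result types.

#' Plot a Kaplan-Meier fit
#'
#' Step curves of survival probability over time, one per methylation
#' group, with censoring ticks.
#'
#' @param object A `km_fit` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  df <- as_tibble(object)
  if (!"group" %in% names(df)) df$group <- "all"
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                        colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = filter(df, .data$n_censor > 0), shape = 3, show.legend = FALSE
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
  p
}

#' Plot a dose-response curve
#'
#' Mean viability with SD error bars per dose and the 50% reference line.
#'
#' @param object A `dose_response` from [normalize_viability()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dose_response
#' @export
autoplot.dose_response <- function(object, ...) {
  curve <- attr(object, "mean_curve")
  ggplot2::ggplot(curve, ggplot2::aes(.data$dose, .data$viability)) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$viability - .data$sd,
                   ymax = .data$viability + .data$sd),
      width = 0.02 * max(curve$dose)
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Dose (µg/mL)", y = "Viability (% of control)") +
    ggplot2::theme_minimal()
}

#' Plot the candidate funnel
#'
#' Bar chart of the gene count surviving each funnel stage, annotated with
#' the percentage of the previous stage.
#'
#' @param object A `funnel_result` from [run_funnel()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot funnel_result
#' @export
autoplot.funnel_result <- function(object, ...) {
  df <- object$stages |>
    mutate(
      stage = factor(.data$stage, levels = rev(.data$stage)),
      label = if_else(is.na(.data$pct_prev), as.character(.data$n),
                      sprintf("%d (%d%%)", .data$n, .data$pct_prev))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$n, .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), hjust = -0.1) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.2))) +
    ggplot2::labs(x = "Genes", y = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `de_result` from [differential_expression()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$logFC, -log10(.data$q),
                                   colour = .data$de)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR") +
    ggplot2::theme_minimal()
}
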