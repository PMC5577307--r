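# ggplot2 views of the main result types.

#' Scatterplot of RTL against parental age at conception
#'
#' @param data phenotype tibble with `rtl` and `mac`/`pac`.
#' @param which `"PAC"` or `"MAC"`.
#' @param jitter_width horizontal jitter (ages are year integers).
#' @return a ggplot.
#' @export
plot_parental_age <- function(data, which = c("PAC", "MAC"), jitter_width = 0.2) {
  which <- match.arg(which)
  xcol <- if (which == "PAC") "pac" else "mac"
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[xcol]], y = .data$rtl)) +
    ggplot2::geom_jitter(width = jitter_width, height = 0, alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE, colour = "steelblue") +
    ggplot2::labs(
      x = sprintf("%s (years)", which),
      y = "relative telomere length"
    ) +
    ggplot2::theme_minimal()
}

#' Plot amplification curves for a set of wells
#'
#' @param curves long-format curve tibble.
#' @param wells optional character vector of `well_id`s to show (default:
#'   first 12).
#' @param threshold optional horizontal threshold line.
#' @param log_y log-scale fluorescence axis.
#' @return a ggplot.
#' @export
plot_amplification <- function(curves, wells = NULL, threshold = NULL,
                               log_y = FALSE) {
  check_curves(curves)
  if (is.null(wells)) wells <- head(unique(curves$well_id), 12)
  df <- curves %>% filter(.data$well_id %in% wells)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cycle, y = .data$fluorescence,
    group = .data$well_id, colour = .data$amplicon
  )) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "cycle", y = "fluorescence") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
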