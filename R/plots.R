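#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Genome-wide window z-score track for a sample call
#'
#' Plots per-window z-scores along the genome, with called CNV segments
#' overlaid and the ±`cnv_z_cutoff` band marked.
#'
#' @param object A `nipt_call`.
#' @param config A [nipt_config()] (for the cutoff lines).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nipt_call <- function(object, config = nipt_config(), ...) {
  wz <- dplyr::mutate(
    object$window_z,
    chrom = factor(.data$chrom, levels = .valid_chroms)
  )
  p <- ggplot2::ggplot(wz, ggplot2::aes(x = .data$start / 1e6, y = .data$z)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * config$cnv_z_cutoff,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x", switch = "x") +
    ggplot2::labs(x = "position (Mb)", y = "window z",
                  title = object$sample_id) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(panel.spacing.x = ggplot2::unit(0.5, "pt"),
                   axis.text.x = ggplot2::element_blank())
  if (nrow(object$cnv) > 0) {
    seg <- dplyr::mutate(object$cnv,
                         chrom = factor(.data$chrom, levels = .valid_chroms))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$Z, yend = .data$Z, colour = .data$type),
      linewidth = 1.2
    )
  }
  p
}

#' Fetal fraction versus gestational age
#'
#' Scatter of fetal fraction against gestational age with a linear trend,
#' annotated with the Pearson correlation.
#'
#' @param records Cohort record tibble with `ga_weeks` and `ff`.
#' @return A ggplot object.
#' @export
plot_ff_vs_ga <- function(records) {
  r <- pearson_r(records$ga_weeks, records$ff)
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$ga_weeks, y = 100 * .data$ff)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick",
                         se = FALSE) +
    ggplot2::labs(x = "gestational age (weeks)", y = "fetal fraction (%)",
                  subtitle = sprintf("Pearson r = %.4f", r)) +
    ggplot2::theme_minimal()
}

#' Per-class screening performance bar chart
#'
#' @param report A `nipt_report` from [stratified_report()].
#' @return A ggplot object showing PPV per called class.
#' @export
plot_class_ppv <- function(report) {
  df <- dplyr::filter(report$by_class, !is.na(.data$ppv))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$class, -.data$ppv),
                                   y = 100 * .data$ppv)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d", .data$TP, .data$P)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "PPV (%)") +
    ggplot2::theme_minimal()
}
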