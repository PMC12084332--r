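## ggplot2 visualisations for the main result types.

#' Plot a calibration fit
#'
#' Calibration points with the fitted line; the subtitle reports slope,
#' R-squared, LLOD and LLOQ.
#'
#' @param object A `calibration_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.calibration_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope,
      colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "concentration ratio (analyte / ISTD)",
      y = "response ratio (peak area analyte / ISTD)",
      title = if (!is.na(object$analyte)) object$analyte else "Calibration",
      subtitle = sprintf(
        "slope %.3g, R² %.4f, LLOD %.3g, LLOQ %.3g",
        object$slope, object$r_squared, object$llod, object$lloq
      )
    ) +
    ggplot2::theme_minimal()
}

#' m/z-CCS map of a 4D library
#'
#' Each GSL series occupies a distinct region of the m/z-CCS plane; this is
#' the two-dimensional projection used to eyeball class separation.
#'
#' @param lib A library tibble.
#' @return A ggplot object.
#' @export
plot_library_map <- function(lib) {
  dat <- lib[!is.na(lib$mz) & !is.na(lib$ccs_A2), , drop = FALSE]
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$mz, y = .data$ccs_A2, colour = .data$series)
  ) +
    ggplot2::geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::labs(
      x = "m/z", y = "CCS (Å²)", colour = "series"
    ) +
    ggplot2::theme_minimal()
}

#' ISTD partition distribution
#'
#' Per-ISTD fraction-2 partition percentages across samples or replicate
#' extracts.
#'
#' @param partition A [partition_records()] tibble.
#' @return A ggplot object.
#' @export
plot_partitions <- function(partition) {
  ggplot2::ggplot(
    partition,
    ggplot2::aes(x = .data$istd, y = .data$A_pct)
  ) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "partition in fraction 2 (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Replicate CV distribution
#'
#' Per-species CVs with the acceptance threshold line.
#'
#' @param cv A result of [cv_table()].
#' @return A ggplot object.
#' @export
plot_cv <- function(cv) {
  dat <- cv$per_species[!is.na(cv$per_species$cv_pct), , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cv_pct)) +
    ggplot2::geom_histogram(binwidth = 5, boundary = 0, fill = "grey70") +
    ggplot2::geom_vline(
      xintercept = cv$threshold_pct, linetype = 2, colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "CV (%)", y = "species",
      subtitle = sprintf(
        "%.1f%% of species below %g%% CV", cv$pct_below, cv$threshold_pct
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
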