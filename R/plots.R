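# ggplot2 helpers for the main result types.

#' Plot germline vs somatic context mutation rates
#'
#' Scatter of per-context somatic rate against germline rate, coloured by
#' alternate allele; CpG>T contexts are omitted by default (their rates
#' dwarf all others).
#'
#' @param rates A [context_rates()] table.
#' @param omit_cpg_t Drop CpG>T contexts (default TRUE).
#' @param log_scale Use log-log axes (default TRUE).
#' @return A ggplot object.
#' @export
plot_rate_scatter <- function(rates, omit_cpg_t = TRUE, log_scale = TRUE) {
  df <- rate_scatter_report(rates)
  if (omit_cpg_t) df <- dplyr::filter(df, !.data$omit_from_plot)
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$germline_rate, y = .data$somatic_rate,
      colour = .data$alt_allele
    )
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::labs(
      x = "germline mutation rate", y = "somatic mutation rate",
      colour = "alt allele"
    ) +
    ggplot2::theme_minimal()
  if (log_scale) {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}

#' Histogram of per-sample Forbes coefficients
#'
#' @param per_sample Tibble from [per_sample_forbes()].
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_per_sample_forbes <- function(per_sample, bins = 30) {
  ggplot2::ggplot(per_sample, ggplot2::aes(x = .data$coefficient)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "per-sample Forbes coefficient", y = "samples"
    ) +
    ggplot2::theme_minimal()
}

#' Shared-variant rate against matched-normal read depth
#'
#' Black points: observed shared rate per depth bin. If a
#' [context_confound_by_depth()] table is supplied, its
#' context-standardized predicted rate is overlaid in grey.
#'
#' @param per_depth Tibble from [shared_rate_by_depth()].
#' @param confound Optional tibble from [context_confound_by_depth()].
#' @param min_calls Hide bins with fewer calls than this (default 20).
#' @return A ggplot object.
#' @export
plot_shared_rate_by_depth <- function(per_depth, confound = NULL,
                                      min_calls = 20) {
  df <- dplyr::filter(per_depth, .data$s_d >= min_calls)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$rate)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "matched-normal read depth", y = "shared variant rate"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(confound)) {
    cf <- dplyr::filter(confound, .data$n_calls >= min_calls)
    p <- p + ggplot2::geom_point(
      data = cf,
      mapping = ggplot2::aes(x = .data$depth, y = .data$predicted_rate),
      colour = "grey60", size = 0.8
    )
  }
  p
}

#' Plot a shared-variant decomposition
#'
#' Expected shared count per partition level against the observed total.
#'
#' @param object Tibble from [forbes_decomposition()].
#' @param b Observed shared total (drawn as a horizontal line when given).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_decomposition <- function(object, b = NULL, ...) {
  df <- dplyr::mutate(
    object,
    level = factor(.data$level, levels = .data$level)
  )
  p <- ggplot2::ggplot(
    df, ggplot2::aes(x = .data$level, y = .data$expected)
  ) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = "partition scheme", y = "expected shared variants"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(b)) {
    p <- p + ggplot2::geom_hline(yintercept = b, linetype = "dashed")
  }
  p
}
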