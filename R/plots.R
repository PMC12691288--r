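#' Plot an indel spectrum
#'
#' Bar chart of the decomposed allele fractions by indel size, with
#' significant indels (and the unedited peak) highlighted; the subtitle
#' reports R-squared and aggregate editing efficiency.
#'
#' @param fit A `tide_fit` from [tide_decompose()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_indel_spectrum <- function(fit, ...) {
  stopifnot(inherits(fit, "tide_fit"))
  d <- tidy(fit) |>
    mutate(status = dplyr::case_when(
      .data$indel == 0 ~ "unedited",
      .data$significant ~ "significant indel",
      TRUE ~ "not significant"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$indel, y = 100 * .data$fraction,
                                  fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      "unedited" = "grey40", "significant indel" = "#d1495b",
      "not significant" = "grey80")) +
    ggplot2::labs(
      x = "indel size (bp)", y = "allele fraction (%)", fill = NULL,
      title = "Indel spectrum by trace decomposition",
      subtitle = sprintf("R² = %.3f; editing efficiency = %.1f%%%s",
                         fit$r2, fit$efficiency_pct,
                         if (fit$interpretable) "" else " (below R² gate)")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_indel_spectrum
#' @param object A `tide_fit`.
#' @exportS3Method ggplot2::autoplot
autoplot.tide_fit <- function(object, ...) plot_indel_spectrum(object, ...)

#' Volcano plot of per-transcript differential expression
#'
#' @param de Output of [transcript_de()].
#' @param alpha,fc_threshold Thresholds drawn as guide lines.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, alpha = 0.05, fc_threshold = 1.5) {
  d <- de |>
    filter(is.finite(.data$rate_ratio), .data$rate_ratio > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$rate_ratio),
                                  y = -log10(.data$q_value),
                                  colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_threshold),
                        linetype = 2) +
    ggplot2::scale_colour_manual(values = c(up = "#d1495b",
                                            down = "#00798c", ns = "grey70")) +
    ggplot2::labs(x = "log2 rate ratio (clone / control)",
                  y = "-log10 adjusted p", colour = NULL,
                  title = "Per-transcript Poisson differential expression") +
    ggplot2::theme_minimal()
}

#' Bar chart of top enriched categories
#'
#' @param res Output of [enrich()].
#' @param top_n Number of categories shown (default 10).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(res, top_n = 10) {
  d <- head(res, top_n) |>
    mutate(category = stats::reorder(.data$category, .data$enrichment_score))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$enrichment_score,
                                  y = .data$category)) +
    ggplot2::geom_col(fill = "#00798c") +
    ggplot2::labs(x = expression(-ln(italic(p))), y = NULL,
                  title = "Over-represented categories") +
    ggplot2::theme_minimal()
}

#' Per-replicate pseudouridylation levels by group
#'
#' @param psi_tbl Output of [psi_per_sample()].
#' @return A ggplot object.
#' @export
plot_psi <- function(psi_tbl) {
  ggplot2::ggplot(psi_tbl, ggplot2::aes(x = .data$group,
                                        y = .data$percent_psi)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7, colour = "#00798c") +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "pseudouridylation (%)",
                  title = "Site-specific pseudouridylation by group") +
    ggplot2::theme_minimal()
}
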