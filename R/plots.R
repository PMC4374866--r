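#' Plot a probe profile with optional segment overlay
#'
#' Probe log2 ratios along the genome, faceted by chromosome, with the
#' fitted segment means drawn on top when segments are supplied.
#'
#' @param profile A `cnv_profile`.
#' @param segments Optional `cnv_segments` for the same sample.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, segments = NULL) {
  df <- as_tibble(profile)
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                         y = .data$log2ratio)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5, colour = "grey40") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "log2 ratio",
                  title = attr(profile, "sample_id")) +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    sd <- as_tibble(segments)
    sd$chrom <- factor(sd$chrom, levels = levels(df$chrom))
    gg <- gg + ggplot2::geom_segment(
      data = sd,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$mean_log2, yend = .data$mean_log2),
      colour = "firebrick", linewidth = 0.9)
  }
  gg
}

#' @export
#' @method autoplot cnv_segments
#' @importFrom ggplot2 autoplot
autoplot.cnv_segments <- function(object, ...) {
  df <- as_tibble(object)
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                                   y = .data$mean_log2, yend = .data$mean_log2,
                                   colour = .data$state)) +
    ggplot2::geom_segment(linewidth = 1.2) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_colour_manual(values = c(LOSS = "#2166ac", NEUTRAL = "grey60",
                                            GAIN = "#b2182b", AMP = "#67001f"),
                                 na.value = "grey80") +
    ggplot2::labs(x = "position (Mb)", y = "segment mean log2",
                  title = attr(object, "sample_id")) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' Plot genotype contrasts of a cohort summary
#'
#' Bar chart of chromothripsis, BFB and LOH counts per genotype, the
#' cohort-level analogue of the per-signature figures the package
#' reproduces.
#'
#' @param summary A `cohort_summary` from [summarize_cohort()].
#' @return A ggplot object.
#' @export
plot_cohort_signatures <- function(summary) {
  df <- summary$signature_counts |>
    tidyr::pivot_longer(c("n_chromothripsis", "n_bfb"),
                        names_to = "signature", values_to = "n") |>
    mutate(signature = dplyr::recode(.data$signature,
                                     n_chromothripsis = "chromothripsis",
                                     n_bfb = "BFB"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signature, y = .data$n,
                                   fill = .data$genotype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "tumors with signature", fill = "genotype") +
    ggplot2::theme_minimal()
}

#' Plot per-sample telomere-length estimates by group
#'
#' @param estimates Tibble of [estimate_telomeres()] rows with an added
#'   `genotype` column.
#' @return A ggplot object.
#' @export
plot_telomere_lengths <- function(estimates) {
  ggplot2::ggplot(estimates, ggplot2::aes(x = .data$genotype,
                                          y = .data$telomere_length / 1e3)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::labs(x = "genotype", y = "mean telomere length (kb)") +
    ggplot2::theme_minimal()
}
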