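# ggplot2 views of the main result types.

#' Bootstrap mean vs standard deviation of TE divergence
#'
#' The classic significance scatter: each point is an isoform pair, placed
#' at its bootstrap mean (x) and bootstrap standard deviation (y) for one
#' replicate; significant pairs are highlighted.
#'
#' @param pairs Pair tibble from [te_divergence_test()].
#' @param replicate Which replicate's summaries to plot (default 1).
#' @return A ggplot object.
#' @export
plot_divergence <- function(pairs, replicate = 1) {
  mu <- paste0("boot_mean_rep", replicate)
  sg <- paste0("boot_sd_rep", replicate)
  ggplot2::ggplot(pairs, ggplot2::aes(.data[[mu]], .data[[sg]],
                                      colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#2166ac")) +
    ggplot2::labs(x = "bootstrap mean log2 TE fold change",
                  y = "bootstrap SD", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Bar plot of the MARS variance decomposition
#'
#' @param decomp Tibble from [variance_decomposition()].
#' @return A ggplot object.
#' @export
plot_variance_decomposition <- function(decomp) {
  d <- decomp |>
    tidyr::pivot_longer(c("individual", "cumulative", "delta"),
                        names_to = "kind", values_to = "r_squared") |>
    mutate(feature = factor(.data$feature, levels = decomp$feature),
           kind = factor(.data$kind, c("individual", "cumulative", "delta")))
  ggplot2::ggplot(d, ggplot2::aes(.data$feature, .data$r_squared,
                                  fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "variance of TE divergence explained") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Fraction profile of selected isoforms
#'
#' Normalized tag counts across the seven gradient fractions, one line per
#' isoform; useful to eyeball why two isoforms of a gene diverge in TE.
#'
#' @param counts Long tibble (`isoform`, `replicate`, `fraction`, and a
#'   `norm_count` or `count` column).
#' @param isoforms Character vector of isoform ids to show.
#' @return A ggplot object.
#' @export
plot_fraction_profile <- function(counts, isoforms) {
  val <- if ("norm_count" %in% names(counts)) "norm_count" else "count"
  d <- counts |>
    filter(.data$isoform %in% isoforms) |>
    group_by(.data$isoform, .data$replicate) |>
    mutate(frac_share = .data[[val]] / sum(.data[[val]])) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$fraction, .data$frac_share,
                                  colour = .data$isoform,
                                  linetype = factor(.data$replicate))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = 1:7) +
    ggplot2::labs(x = "gradient fraction", y = "share of isoform tags",
                  linetype = "replicate") +
    ggplot2::theme_minimal()
}
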