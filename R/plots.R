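# ggplot2 views of the main result types

#' @describeIn pca_genotypes autoplot: PC scatter colored by population.
#' @param object a `capri_pca`.
#' @param x,y components to plot.
#' @param ... unused.
#' @export
autoplot.capri_pca <- function(object, x = "PC1", y = "PC2", ...) {
  vf <- object$variance_fraction
  lab <- function(pc) {
    k <- as.integer(sub("PC", "", pc))
    sprintf("%s (%.1f%%)", pc, 100 * vf[k])
  }
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data[[x]], .data[[y]], colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = lab(x), y = lab(y), colour = "population") +
    ggplot2::theme_minimal()
}

#' @describeIn admixture_em autoplot: stacked ancestry bar plot.
#' @param object a `capri_admixture`.
#' @param ... unused.
#' @export
autoplot.capri_admixture <- function(object, ...) {
  long <- tidy(object)
  ord <- long %>%
    filter(.data$cluster == "Q1") %>%
    arrange(.data$population, dplyr::desc(.data$ancestry)) %>%
    pull(.data$sample_id)
  long$sample_id <- factor(long$sample_id, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$ancestry,
                                     fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~population, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "ancestry fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(1, "pt"))
}

#' Plot an LD decay profile
#'
#' @param profile tibble from [ld_decay_profile()].
#' @return A ggplot.
#' @export
plot_ld_decay <- function(profile) {
  dec <- attr(profile, "decay_r2") %||% 0.25
  df <- profile[profile$n_pairs > 0, ]
  ggplot2::ggplot(df, ggplot2::aes((.data$bin_start + .data$bin_end) / 2e3,
                                   .data$mean_r2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = dec, linetype = "dashed") +
    ggplot2::labs(x = "inter-variant distance (kb)",
                  y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of windowed scan p-values
#'
#' @param windows tibble from [rank_pvalues()].
#' @param threshold_neg_log10 significance line.
#' @return A ggplot.
#' @export
plot_scan_windows <- function(windows, threshold_neg_log10 = 2) {
  df <- windows[!is.na(windows$neg_log10_p), ]
  df$chromosome <- factor(df$chromosome,
                          levels = unique(df$chromosome[chrom_order(df$chromosome)]))
  ggplot2::ggplot(df, ggplot2::aes((.data$start_bp + .data$end_bp) / 2e6,
                                   .data$neg_log10_p, colour = .data$chromosome)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::facet_grid(~chromosome, scales = "free_x", space = "free_x") +
    ggplot2::geom_hline(yintercept = threshold_neg_log10, linetype = "dashed") +
    ggplot2::labs(x = "window midpoint (Mb)", y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing.x = ggplot2::unit(1, "pt"))
}

#' Per-population F_ROH distribution plot
#'
#' @param froh_genome tibble `sample_id`, `froh` from [froh()].
#' @param samples sample sheet with `sample_id`, `population`.
#' @return A ggplot.
#' @export
plot_froh <- function(froh_genome, samples) {
  df <- left_join(froh_genome, samples, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$population, .data$froh,
                                   fill = .data$population)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = expression(F[ROH])) +
    ggplot2::theme_minimal()
}
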