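#' TSS metaprofile of DMS against all surveyed sites
#'
#' Binned relative-frequency curves of signed TSS distances for a site set
#' (typically the DMS) and the full catalog, the standard view of where
#' differential methylation concentrates relative to promoters.
#'
#' @param dms Tibble of DMS sites (`chrom`, `pos`).
#' @param catalog Full site catalog.
#' @param genes Gene annotation.
#' @param span,bin Profile geometry, see [binned_profile()].
#' @return Tibble with `bin_start`, `bin_end`, `midpoint`, `freq`, `set`
#'   ("DMS"/"all sites"), ready for [plot_tss_profile()].
#' @export
tss_profile <- function(dms, catalog, genes, span = 3000, bin = 100) {
  one <- function(sites, label) {
    pr <- binned_profile(distance_to_tss(sites, genes), span, bin)
    pr$midpoint <- (pr$bin_start + pr$bin_end) / 2
    pr$set <- label
    pr
  }
  dplyr::bind_rows(one(dms, "DMS"), one(catalog, "all sites"))
}

#' @rdname tss_profile
#' @param profile Output of [tss_profile()].
#' @return A ggplot object.
#' @export
plot_tss_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$midpoint, y = .data$freq,
                               colour = .data$set)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c("DMS" = "firebrick",
                                            "all sites" = "steelblue")) +
    ggplot2::labs(x = "distance to TSS (nt)", y = "relative frequency",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise replicate r-squared
#'
#' @param r2 Tibble from [replicate_r2()].
#' @return A ggplot object.
#' @export
plot_replicate_r2 <- function(r2) {
  ggplot2::ggplot(r2, ggplot2::aes(x = .data$library_a, y = .data$library_b,
                                   fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r2)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(r^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Volcano-style view of a DMS fit
#'
#' Difference of normalized means against `-log10(p)`, coloured by
#' direction call.
#'
#' @param object An `mscc_dms` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mscc_dms
#' @export
autoplot.mscc_dms <- function(object, ...) {
  tab <- dplyr::filter(object$table, .data$passed_filter)
  ggplot2::ggplot(tab,
                  ggplot2::aes(x = .data$mean_treated - .data$mean_control,
                               y = -log10(.data$p),
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(methylated = "firebrick",
                                            demethylated = "steelblue",
                                            none = "grey70")) +
    ggplot2::labs(x = "treated - control normalized digestion frequency",
                  y = expression(-log[10](p)), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Null distribution of the TSS-proximity statistic
#'
#' Histogram of the simulated near-TSS fractions with the observed value
#' marked.
#'
#' @param object An `mscc_perm` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mscc_perm
#' @export
autoplot.mscc_perm <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$t_observed,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "fraction of sites near TSS (null draws)",
                  y = "simulations") +
    ggplot2::theme_minimal()
}
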