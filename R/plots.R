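#' Plot methods for package results
#'
#' ggplot2 `autoplot()` methods and `plot_*()` helpers: PCA scatter, ROH
#' length distributions, the N_E trajectory, the weighted-LD decay fit and
#' per-haplotype ancestry tracks.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name admixbreed-plots
NULL

#' @rdname admixbreed-plots
#' @method autoplot gm_pca
#' @export
autoplot.gm_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname admixbreed-plots
#' @param rohset A [detect_roh()] result.
#' @param bin_kb Histogram bin width (kb).
#' @export
plot_roh_lengths <- function(rohset, bin_kb = 500) {
  ggplot2::ggplot(rohset,
                  ggplot2::aes(.data$length_bp / 1000, colour = .data$group)) +
    ggplot2::geom_freqpoly(binwidth = bin_kb) +
    ggplot2::labs(x = "ROH length (kb)", y = "count", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname admixbreed-plots
#' @method autoplot ne_trajectory
#' @export
autoplot.ne_trajectory <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$ne)),
                  ggplot2::aes(.data$t, .data$ne)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "generations ago (t = 1 / 2c)",
                  y = expression(N[E])) +
    ggplot2::theme_minimal()
}

#' @rdname admixbreed-plots
#' @method autoplot admixture_date
#' @export
autoplot.admixture_date <- function(object, ...) {
  bins <- object$bins
  co <- object$fit
  curve <- tibble(
    d = seq(min(bins$d), max(bins$d), length.out = 200)
  ) |>
    mutate(stat = co[["a"]] * exp(-co[["g"]] * .data$d) + co[["k"]])
  ggplot2::ggplot(bins, ggplot2::aes(.data$d, .data$stat)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(
      x = "genetic distance (Morgans)", y = "weighted admixture LD",
      title = sprintf("fitted decay: g = %.1f generations", object$generations)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname admixbreed-plots
#' @param track An [deconvolve()] result.
#' @export
plot_ancestry_tracks <- function(track) {
  ggplot2::ggplot(track,
                  ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                               ymin = 0, ymax = 1, fill = .data$call)) +
    ggplot2::geom_rect() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$hap_id),
                        cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(wolf = "#444444", dog = "#c8a165",
                                          uncalled = "#eeeeee")) +
    ggplot2::labs(x = "position (Mb)", y = NULL, fill = "ancestry") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   strip.text.y = ggplot2::element_text(angle = 0))
}
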