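#' Classification scatter of allele-frequency shifts
#'
#' Plots ambient against hot regime-level shifts per SNP, coloured by the
#' four-class scheme, facetted by pollination regime, with the calibrated
#' thresholds as dashed guides.
#'
#' @param classes Classification tibble from [classify_shifts()] /
#'   [scan_selection()].
#' @param thresholds Optional threshold tibble; when supplied, the mean
#'   effective threshold per regime is drawn.
#' @return A ggplot object.
#' @export
plot_classification <- function(classes, thresholds = NULL) {
  pal <- c(background = "grey70", global_adaptation = "forestgreen",
           conditional_ambient = "steelblue", conditional_hot = "firebrick",
           antagonistic_pleiotropy = "purple")
  p <- ggplot2::ggplot(classes,
                       ggplot2::aes(.data$daf_ambient, .data$daf_hot,
                                    colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = pal, drop = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$pollination)) +
    ggplot2::labs(x = expression(Delta * "AF (ambient)"),
                  y = expression(Delta * "AF (hot)"), colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    thr <- thresholds |>
      dplyr::group_by(.data$pollination, .data$temperature) |>
      dplyr::summarise(thr = mean(.data$daf_effective), .groups = "drop")
    amb <- dplyr::filter(thr, .data$temperature == "ambient")
    hot <- dplyr::filter(thr, .data$temperature == "hot")
    if (nrow(amb)) {
      p <- p + ggplot2::geom_vline(
        data = amb, ggplot2::aes(xintercept = .data$thr),
        linetype = "dotted") +
        ggplot2::geom_vline(
          data = amb, ggplot2::aes(xintercept = -.data$thr),
          linetype = "dotted")
    }
    if (nrow(hot)) {
      p <- p + ggplot2::geom_hline(
        data = hot, ggplot2::aes(yintercept = .data$thr),
        linetype = "dotted") +
        ggplot2::geom_hline(
          data = hot, ggplot2::aes(yintercept = -.data$thr),
          linetype = "dotted")
    }
  }
  p
}

#' Manhattan plot of the replicated CMH scan
#'
#' @param tests Test tibble from [cmh_scan()] / [scan_selection()].
#' @param fdr FDR level for the guide line (default 0.05).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(tests, fdr = 0.05) {
  dat <- dplyr::filter(tests, !is.na(.data$p))
  sig_p <- dat |>
    dplyr::filter(.data$q < fdr) |>
    dplyr::pull(.data$p)
  ggplot2::ggplot(dat,
                  ggplot2::aes(.data$pos / 1e6, -log10(.data$p),
                               colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.7, show.legend = FALSE) +
    ggplot2::scale_colour_manual(
      values = rep(c("grey20", "grey60"),
                   length.out = dplyr::n_distinct(dat$chrom))) +
    {if (length(sig_p))
      ggplot2::geom_hline(yintercept = -log10(max(sig_p)),
                          linetype = "dashed", colour = "red")} +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$pollination),
      cols = ggplot2::vars(.data$temperature, .data$chrom),
      scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` for the package's result objects: null distributions show
#' the |dAF| histogram with its 95th percentile; PCA results show the pool
#' scores on the first two axes; scan results show the Manhattan plot.
#'
#' @param object A driftscan result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name driftscan-autoplot
NULL

#' @rdname driftscan-autoplot
#' @export
autoplot.driftscan_null <- function(object, ...) {
  q95 <- neutral_quantile(object, 0.95, "daf")
  ggplot2::ggplot(tibble::tibble(daf = object$daf),
                  ggplot2::aes(.data$daf)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey60") +
    ggplot2::geom_vline(xintercept = q95, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "|\u0394AF| under neutral drift", y = "SNPs",
                  title = sprintf("95th percentile = %.3f", q95)) +
    ggplot2::theme_minimal()
}

#' @rdname driftscan-autoplot
#' @export
autoplot.driftscan_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               label = .data$pool_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_frac[1]),
      y = sprintf("PC2 (%.1f%%)",
                  100 * (if (length(object$var_frac) > 1)
                    object$var_frac[2] else 0))) +
    ggplot2::theme_minimal()
}

#' @rdname driftscan-autoplot
#' @export
autoplot.driftscan_scan <- function(object, ...) {
  plot_manhattan(object$tests)
}
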