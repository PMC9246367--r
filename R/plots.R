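#' Plot a rate-ratio fit against the equilibrium curve
#'
#' Observed per-bin rate ratios (with SE bars when available) overlaid on
#' the fitted `r(FST; r0)` curve.
#'
#' @param object A `rate_fit` from [fit_r0()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rate_fit
#' @export
autoplot.rate_fit <- function(object, ...) {
  curve <- tibble::tibble(fst = seq(0, 1, length.out = 200))
  curve$r <- r_from_fst(curve$fst, object$r0_hat)
  p <- ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$fst, y = .data$r)) +
    ggplot2::geom_line(data = curve, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(F[ST]), y = "observed rate ratio r",
      title = sprintf("Equilibrium IM fit: r0 = %.3f", object$r0_hat)) +
    ggplot2::theme_minimal()
  if ("se" %in% names(object$bins)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$r - .data$se, ymax = .data$r + .data$se),
      width = 0.015)
  }
  p
}

#' @export
#' @rdname autoplot.rate_fit
plot.rate_fit <- function(x, ...) print(autoplot(x, ...))

#' D statistics as a function of the FST threshold
#'
#' Reproduces the cumulative-threshold scan: D3 and D4 (with jackknife SE
#' ribbons) on SNPs whose background FST is at least each threshold.
#'
#' @param d_by_threshold The `d_by_threshold` tibble from [run_dstats()].
#' @return A ggplot object.
#' @export
plot_dstat_scan <- function(d_by_threshold) {
  long <- tidyr::pivot_longer(
    d_by_threshold,
    cols = c("d3", "d4"), names_to = "statistic", values_to = "estimate")
  long$se <- ifelse(long$statistic == "d3", long$d3_se, long$d4_se)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$estimate,
                                     colour = .data$statistic)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$estimate - .data$se,
                   ymax = .data$estimate + .data$se,
                   fill = .data$statistic), alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$site_class)) +
    ggplot2::labs(x = expression("background" ~ F[ST] ~ "threshold"),
                  y = "D statistic") +
    ggplot2::theme_minimal()
}

#' FST landscape along chromosomes
#'
#' @param window_stats Window tibble from [windowed_stats()].
#' @return A ggplot object.
#' @export
plot_fst_landscape <- function(window_stats) {
  ggplot2::ggplot(window_stats,
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$fst)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(F[ST])) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Entropy against a divergence statistic across segments
#'
#' Scatter of per-segment entropy (Sw or Sb) versus pi, DXY or FST with a
#' linear trend, the visual companion of the jackknife correlations of
#' [run_entropy()].
#'
#' @param segment_entropy The `segment_entropy` element of [run_entropy()]
#'   joined with the segment statistics (must contain the two plotted
#'   columns).
#' @param entropy Column name of the entropy axis (default `"sb_mean"`).
#' @param statistic Column name of the divergence axis (default `"fst"`).
#' @return A ggplot object.
#' @export
plot_entropy_correlation <- function(segment_entropy, entropy = "sb_mean",
                                     statistic = "fst") {
  ggplot2::ggplot(segment_entropy,
                  ggplot2::aes(x = .data[[entropy]],
                               y = .data[[statistic]])) +
    ggplot2::geom_point(alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", na.rm = TRUE) +
    ggplot2::labs(x = entropy, y = statistic) +
    ggplot2::theme_minimal()
}
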