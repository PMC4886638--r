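#' Plot a fitted 5PL standard curve
#'
#' Curve on a log10 concentration axis with the standards' fluorescence span
#' and, when available, the LOD marked.
#'
#' @param object A `fivepl_fit`.
#' @param n Points along the curve.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fivepl_fit
#' @export
autoplot.fivepl_fit <- function(object, n = 200L, ...) {
  conc <- object$ec50 * 10^seq(-3, 3, length.out = n)
  df <- tibble::tibble(conc = conc, fluorescence = predict(object, conc))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$conc, y = .data$fluorescence)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::geom_hline(yintercept = object$standards_fl_range,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "concentration (pg/ml)", y = "fluorescence (MFI)",
                  title = "5PL standard curve",
                  subtitle = "dashed: fluorescence span of the standards")
  if (is.finite(object$lod_fl)) {
    p <- p + ggplot2::geom_hline(yintercept = object$lod_fl,
                                 linetype = "dotted", colour = "red")
  }
  p
}

#' Plot a rank-difference profile
#'
#' Log2 of successive differences of the unique sorted responses against
#' rank; a detection floor would pull the left of the profile toward -Inf,
#' half-unit quantisation pins it at -1.
#'
#' @param object A `rank_diff_profile` from [rank_difference_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rank_diff_profile
#' @export
autoplot.rank_diff_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$rank, y = .data$log2_diff)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = attr(object, "head_mean"),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "rank", y = "log2 rank difference",
                  subtitle = sprintf("head mean = %.3f",
                                     attr(object, "head_mean")))
}

#' Plot a translation scan
#'
#' -log10 p-values of the concentration-scale t-test across response levels,
#' with the (constant) fluorescence-scale p-value as the reference line.
#'
#' @param object A `sim_scan` from [translation_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sim_scan
#' @export
autoplot.sim_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level)) +
    ggplot2::geom_line(ggplot2::aes(y = -log10(.data$p_conc),
                                    colour = "concentration")) +
    ggplot2::geom_line(ggplot2::aes(y = -log10(.data$p_fl),
                                    colour = "fluorescence"),
                       linetype = "dashed") +
    ggplot2::labs(x = "response level (normalized fluorescence)",
                  y = expression(-log[10](p)),
                  colour = "t-test scale",
                  subtitle = sprintf("skew alpha = %g, n = %d, d = %g",
                                     attr(object, "skew_alpha"),
                                     attr(object, "n_per_group"),
                                     attr(object, "cohen_d")))
}

#' Plot adjusted means with confidence intervals
#'
#' Point-and-interval display of [adjusted_means()] output, optionally
#' faceted by analyte when several analytes are bound together.
#'
#' @param means Tibble from [adjusted_means()] (rows may span analytes).
#' @return A ggplot.
#' @export
plot_adjusted_means <- function(means) {
  ggplot2::ggplot(means, ggplot2::aes(x = .data$level, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "adjusted mean (log2 response)",
                  subtitle = "error bars: 95% confidence")
}

#' Histogram of a p-value uniformity scan
#'
#' @param scan Result of [pvalue_uniformity_scan()].
#' @param bins Histogram bins (default 10).
#' @return A ggplot.
#' @export
plot_pvalue_histogram <- function(scan, bins = 10L) {
  ggplot2::ggplot(scan$pvalues, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, closed = "left",
                            fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "Mann-Whitney p-value", y = "count",
                  subtitle = sprintf("KS vs U(0,1): D = %.3f, p = %.3f",
                                     scan$ks_statistic, scan$ks_pvalue))
}
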