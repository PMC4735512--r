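#' Concentration-sweep summary plot
#'
#' Plots a simulation readout (cluster number, median cluster diameter or
#' bridge contact frequency) against exogenous binder concentration, one
#' point per iteration with a median trend line, in the style of the
#' concentration-response panels used to compare the weak-binding,
#' capping and spreading mechanisms.
#'
#' @param sweep data frame from [run_variant_sweep()] (may contain several
#'   variants).
#' @param metric column to plot (default `"median_diameter"`).
#' @return A ggplot object.
#' @export
plot_concentration_sweep <- function(sweep, metric = "median_diameter") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$N_exog,
                                      y = .data[[metric]])) +
    ggplot2::geom_jitter(width = 0.5, alpha = 0.3, size = 0.8) +
    ggplot2::stat_summary(fun = stats::median, geom = "line",
                          colour = "firebrick") +
    ggplot2::facet_wrap(~variant, scales = "free_y") +
    ggplot2::labs(x = "exogenous binders (N_exog)", y = metric) +
    ggplot2::theme_bw()
}

#' Contact-change ratio track plot
#'
#' @param ratio a [ratio_minus_one()] data frame.
#' @param scheme optional [region_scheme()]; draws the near/far boundary
#'   and viewpoint.
#' @return A ggplot object.
#' @export
plot_ratio_track <- function(ratio, scheme = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- ratio[!ratio$excluded & !is.na(ratio$ratio), ]
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                         y = .data$ratio)) +
    ggplot2::geom_col(width = 200) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "position (bp)", y = "contact ratio - 1") +
    ggplot2::theme_bw()
  if (!is.null(scheme))
    gg <- gg + ggplot2::geom_vline(xintercept = scheme$boundary,
                                   linetype = "dashed") +
      ggplot2::geom_vline(xintercept = mean(scheme$viewpoint),
                          colour = "grey40")
  gg
}

#' Localization-weighted cluster size histogram
#'
#' @param wsd a [weighted_size_distribution()] result.
#' @return A ggplot object showing the fraction of localizations in
#'   clusters of each diameter bin.
#' @export
plot_size_distribution <- function(wsd) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  h <- wsd$histogram
  df <- data.frame(mid = h$mids, frac = h$density)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$frac)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = wsd$weighted_median,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "cluster diameter (nm)",
                  y = "fraction of localizations") +
    ggplot2::theme_bw()
}
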