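#' Plot a fitted trend panel with significant periods
#'
#' Figure in the style of dates-as-data trend plots: fitted trend with its
#' 95% confidence ribbon on a reversed cal BP axis, segments of the fit
#' coloured blue where the population is increasing significantly and red
#' where it is decreasing, vertical dashed markers at the earliest
#' domesticate occurrences, and horizontal bars at the base of the panel
#' for the significant periods of an optional alternate model fit.
#'
#' @param fit A `trend_fit`.
#' @param deriv The matching `deriv_series` from [derivative()].
#' @param periods A `significance_periods` table for `fit`.
#' @param markers Data frame of vertical markers (`label`, `cal_bp`);
#'   default [domestication_markers()]; `NULL` to omit.
#' @param alt_periods Optional `significance_periods` from an alternate
#'   model (e.g. the uncorrected proxy), drawn as horizontal bars at the
#'   base of the panel.
#' @return A ggplot object.
#' @export
plot_trend_panel <- function(fit, deriv, periods, markers = domestication_markers(),
                             alt_periods = NULL) {
  stopifnot(inherits(fit, "trend_fit"))
  grid <- fit$grid
  if (!identical(sort(grid$cal_bp), sort(deriv$cal_bp))) {
    abort("fit and derivative are on different grids.", class = "chronopop_usage_error")
  }
  dir_cols <- c(increase = "#2166ac", decrease = "#b2182b")
  seg <- NULL
  if (nrow(periods) > 0) {
    seg <- purrr::pmap_dfr(periods, function(start, end, direction) {
      g <- grid[grid$cal_bp <= start & grid$cal_bp >= end, , drop = FALSE]
      g$direction <- direction
      g$period_id <- paste(start, end)
      g
    })
  }
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$cal_bp, y = .data$fitted)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      fill = "grey80", alpha = 0.7
    ) +
    ggplot2::geom_line(linewidth = 0.6, colour = "grey25")
  if (!is.null(seg) && nrow(seg) > 0) {
    p <- p + ggplot2::geom_line(
      data = seg,
      ggplot2::aes(group = .data$period_id, colour = .data$direction),
      linewidth = 1.2
    )
  }
  if (!is.null(markers) && nrow(markers) > 0) {
    p <- p + ggplot2::geom_vline(
      data = markers, ggplot2::aes(xintercept = .data$cal_bp),
      linetype = "dashed", colour = "grey40"
    )
  }
  if (!is.null(alt_periods) && nrow(alt_periods) > 0) {
    ybar <- min(grid$lo) * 0.98
    p <- p + ggplot2::geom_segment(
      data = alt_periods,
      ggplot2::aes(
        x = .data$start, xend = .data$end,
        colour = .data$direction
      ),
      y = ybar, yend = ybar, linewidth = 2, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::scale_colour_manual(values = dir_cols, name = NULL) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "Calendar age (cal BP)",
      y = sprintf(
        "%s (%s), fitted %s trend",
        fit$proxy, if (fit$corrected) "corrected" else "observed",
        toupper(fit$kind)
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trend_fit <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$cal_bp)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), size = 0.7, colour = "grey55") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue4") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "Calendar age (cal BP)", y = "Response-scale value",
      title = sprintf(
        "%s %s trend (%s)", toupper(object$kind), object$proxy,
        if (object$corrected) "corrected" else "observed"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot the four population proxies
#'
#' Faceted view of a long proxy table, one panel per proxy type with
#' observed and corrected series overlaid, optionally with bootstrap
#' envelopes.
#'
#' @param proxies A long proxy table from [build_proxies()], optionally
#'   with `lo`/`hi` envelope columns (as written by [run_pipeline()]).
#' @return A ggplot object.
#' @export
plot_proxies <- function(proxies) {
  p <- ggplot2::ggplot(proxies, ggplot2::aes(
    x = .data$cal_bp, y = .data$value,
    colour = .data$corrected
  ))
  if (all(c("lo", "hi") %in% names(proxies))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi, fill = .data$corrected),
      alpha = 0.2, colour = NA
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$proxy, scales = "free_y", ncol = 1) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Calendar age (cal BP)", y = "Proxy value") +
    ggplot2::theme_minimal()
}
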