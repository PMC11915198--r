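# ggplot2 display methods for the main result types.

#' Plot a stop's weather window
#'
#' Line panels of VPD, soil moisture and WFSI over the 10-day window, with
#' the before/after split and the breakpoint timing window shaded.
#'
#' @param object An `fs_window` from [extract_window()].
#' @param timing_window_days Days shaded around the burn day (default
#'   `c(-1, 2)`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fs_window <- function(object, timing_window_days = c(-1, 2), ...) {
  split <- attr(object, "split_index") %||% 120L
  lo <- split - 24 + timing_window_days[1] * 24 + 1
  hi <- split + timing_window_days[2] * 24
  df <- tidyr::pivot_longer(as.data.frame(object)[c("hour", "vpd", "sm", "wfsi")],
                            -"hour", names_to = "variable")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$value)) +
    ggplot2::annotate("rect", xmin = lo, xmax = hi, ymin = -Inf, ymax = Inf,
                      alpha = 0.15) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = split + 0.5, linetype = 2) +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "hour of 10-day window (burn day ends at 120)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot driver contributions of an attribution run
#'
#' Stacked bar of normalized driver shares (summing to 100%, including the
#' unknown category), optionally per year.
#'
#' @param object An `fs_records` tibble.
#' @param by_year Facet by year if a `year` column is present.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fs_records <- function(object, by_year = FALSE, ...) {
  drv <- c(fs_drivers(), "unknown")
  if (by_year && "year" %in% names(object)) {
    df <- annual_series(object)
  } else {
    object$year <- 1L
    df <- annual_series(object)
    df$year <- "all"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$year), y = .data$share,
                                   fill = .data$driver)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "Spectral", drop = FALSE) +
    ggplot2::labs(x = NULL, y = "share of fire stops (%)", fill = "driver") +
    ggplot2::theme_minimal()
}

#' Map a gridded driver summary
#'
#' Tile map of one column of a grid summary (share, flag percentage or
#' explained fraction per equal-area cell).
#'
#' @param summary An `fs_grid_summary` from [grid_aggregate()].
#' @param column Column to map (default `"pct_explained"`).
#' @return A ggplot.
#' @export
plot_grid_summary <- function(summary, column = "pct_explained") {
  stopifnot(column %in% names(summary))
  cs <- attr(summary, "cell_size") %||% 1
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$x_center, y = .data$y_center,
                                        fill = .data[[column]])) +
    ggplot2::geom_tile(width = cs, height = cs) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = column) +
    ggplot2::theme_minimal()
}
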