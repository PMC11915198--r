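# Reporting module: spatial aggregation of attribution records onto
# equal-area grids, seasonal/annual driver-share series, fire-size-class
# summaries, and OLS trends.

fs_contrib_cols <- function() paste0("contrib_", c(fs_drivers(), "unknown"))

#' Aggregate attribution records onto an equal-area grid
#'
#' Summarizes per-stop records on square cells of `cell_size` meters
#' (defaults 20 km, i.e. 400 km2 cells; use 40 km for annual series).
#' Records must be georeferenced in an equal-area projection. Two kinds of
#' percentages are reported, as both are meaningful: `flag_pct_*` uses raw
#' flags (a stop can carry up to four, so driver percentages may sum above
#' 100) and `share_*` uses the normalized contributions (summing to 100 per
#' cell, including the unknown category). `dominant_landscape` names the
#' landscape driver with the largest share in the cell.
#'
#' @param records An `fs_records` tibble (needs `x`, `y`).
#' @param cell_size Cell size in meters (default 20000).
#' @param statistic Which summaries to include: any of `"flag_pct"`,
#'   `"relative_share"`, `"dominant_landscape"` (default all).
#' @return Tibble with `cell_x`, `cell_y` (indices), `x_center`,
#'   `y_center`, `n_stops`, `pct_explained` and the requested columns.
#' @export
grid_aggregate <- function(records, cell_size = 20000,
                           statistic = c("flag_pct", "relative_share",
                                         "dominant_landscape")) {
  statistic <- match.arg(statistic, several.ok = TRUE)
  stopifnot(all(c("x", "y") %in% names(records)))
  drv <- fs_drivers()
  land <- c("downslope", fs_fuel_hierarchy_default())
  df <- records |>
    dplyr::mutate(cell_x = ceiling(.data$x / cell_size),
                  cell_y = ceiling(.data$y / cell_size))
  out <- df |>
    dplyr::group_by(.data$cell_x, .data$cell_y) |>
    dplyr::summarise(
      n_stops = dplyr::n(),
      pct_explained = 100 * mean(.data$explained),
      dplyr::across(dplyr::all_of(drv), ~ 100 * mean(.x),
                    .names = "flag_pct_{.col}"),
      dplyr::across(dplyr::all_of(fs_contrib_cols()),
                    ~ 100 * sum(.x) / dplyr::n(),
                    .names = "share_{.col}"),
      .groups = "drop") |>
    dplyr::rename_with(~ sub("share_contrib_", "share_", .x),
                       dplyr::starts_with("share_contrib_")) |>
    dplyr::mutate(x_center = (.data$cell_x - 0.5) * cell_size,
                  y_center = (.data$cell_y - 0.5) * cell_size,
                  .after = "cell_y")
  share_land <- as.matrix(out[, paste0("share_", land)])
  out$dominant_landscape <- ifelse(rowSums(share_land) > 0,
                                   land[max.col(share_land, "first")],
                                   NA_character_)
  if (!"flag_pct" %in% statistic) {
    out <- dplyr::select(out, -dplyr::starts_with("flag_pct_"))
  }
  if (!"relative_share" %in% statistic) {
    out <- dplyr::select(out, -dplyr::starts_with("share_"))
  }
  if (!"dominant_landscape" %in% statistic) {
    out$dominant_landscape <- NULL
  }
  class(out) <- unique(c("fs_grid_summary", class(out)))
  attr(out, "cell_size") <- cell_size
  out
}

#' Per-period driver contribution series
#'
#' Per year (or per year and month) and per driver: the raw flag percentage
#' and the normalized share of stops (shares include the unknown category
#' and sum to 100 within each period).
#'
#' @param records An `fs_records` tibble with a `year` column (and
#'   `last_burn_date` when `by_month = TRUE`).
#' @param by_month Also split by calendar month of the last burn date.
#' @return Long tibble: `year` (, `month`), `driver`, `flag_pct`, `share`,
#'   `n_stops`.
#' @export
annual_series <- function(records, by_month = FALSE) {
  stopifnot("year" %in% names(records))
  df <- records
  grp <- "year"
  if (by_month) {
    stopifnot("last_burn_date" %in% names(records))
    df$month <- as.integer(format(
      as.Date(df$last_burn_date - 1,
              origin = as.Date(paste0(ifelse(is.na(df$year), 2001, df$year),
                                      "-01-01"))), "%m"))
    grp <- c("year", "month")
  }
  drv <- c(fs_drivers(), "unknown")
  agg <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_stops = dplyr::n(),
      # "unknown" has no raw flag; its flag_pct is the unexplained fraction
      flag_pct.unknown = 100 * mean(!.data$explained),
      dplyr::across(dplyr::all_of(fs_drivers()), ~ 100 * mean(.x),
                    .names = "flag_pct.{.col}"),
      dplyr::across(dplyr::all_of(fs_contrib_cols()),
                    ~ 100 * sum(.x) / dplyr::n(), .names = "share.{.col}"),
      .groups = "drop")
  agg |>
    tidyr::pivot_longer(cols = -dplyr::all_of(c(grp, "n_stops")),
                        names_to = c(".value", "driver"),
                        names_pattern = "(flag_pct|share)\\.(?:contrib_)?(.*)") |>
    dplyr::mutate(driver = factor(.data$driver, levels = drv)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grp)), .data$driver)
}

#' OLS trend of an annual driver-share series
#'
#' Ordinary least squares regression of a yearly percentage series on year.
#'
#' @param series Data frame with the year and value columns.
#' @param value,year Column names (defaults `"share"` and `"year"`).
#' @return An `fs_trend` object wrapping the `lm` fit; `tidy()` gives the
#'   coefficient table, `glance()` a one-row summary with `slope`
#'   (percent/year), `p_value`, `r_squared`, `n_years`.
#' @export
ols_trend <- function(series, value = "share", year = "year") {
  stopifnot(all(c(value, year) %in% names(series)), nrow(series) >= 3)
  d <- data.frame(y = series[[value]], t = series[[year]])
  fit <- stats::lm(y ~ t, data = d)
  if (sd(d$y) <= 1e-12 * max(1, abs(mean(d$y)))) {
    # constant series: zero slope, no explainable variance
    slope <- 0; p <- 1; r2 <- 0
  } else {
    sm <- summary(fit)
    slope <- unname(coef(fit)[2])
    p <- sm$coefficients[2, 4]
    r2 <- sm$r.squared
  }
  structure(list(fit = fit, slope = slope, p_value = p, r_squared = r2,
                 n_years = nrow(d)), class = "fs_trend")
}

#' @export
print.fs_trend <- function(x, ...) {
  cat(sprintf("<fs_trend> slope = %.4g %%/yr, p = %.3g, R2 = %.3f (n = %d)\n",
              x$slope, x$p_value, x$r_squared, x$n_years))
  invisible(x)
}

#' @describeIn ols_trend Coefficient-level summary of the trend fit.
#' @param x An `fs_trend` object.
#' @param ... Unused.
#' @export
tidy.fs_trend <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                 std_error = cf[, 2], statistic = cf[, 3], p_value = cf[, 4])
}

#' @describeIn ols_trend One-row model summary.
#' @export
glance.fs_trend <- function(x, ...) {
  tibble::tibble(slope = x$slope, p_value = x$p_value,
                 r_squared = x$r_squared, n_years = x$n_years)
}

#' Driver shares by fire size class
#'
#' Normalized driver shares per logarithmic fire-size class, linking each
#' record to its fire's burned area.
#'
#' @param records An `fs_records` tibble.
#' @param areas Tibble `fire_id`, `area_km2` (see [fire_areas()]).
#' @param breaks Class edges in km2 (default `c(0, 3, 30, 300, Inf)`).
#' @return Tibble `size_class`, `n_stops`, `driver`, `share`.
#' @export
size_class_summary <- function(records, areas,
                               breaks = c(0, 3, 30, 300, Inf)) {
  df <- dplyr::inner_join(records, areas[, c("fire_id", "area_km2")],
                          by = "fire_id") |>
    dplyr::mutate(size_class = cut(.data$area_km2, breaks = breaks))
  df |>
    dplyr::group_by(.data$size_class) |>
    dplyr::summarise(
      n_stops = dplyr::n(),
      dplyr::across(dplyr::all_of(fs_contrib_cols()),
                    ~ 100 * sum(.x) / dplyr::n(), .names = "{.col}"),
      .groups = "drop") |>
    tidyr::pivot_longer(dplyr::all_of(fs_contrib_cols()),
                        names_to = "driver", values_to = "share",
                        names_prefix = "contrib_")
}

#' Plain-text run report
#'
#' Writes (or returns) a short text summary of an attribution run: stop and
#' exclusion counts, the explained fraction, and per-driver flag
#' percentages and shares.
#'
#' @param records An `fs_records` tibble.
#' @param file Optional path; if `NULL` the lines are returned invisibly.
#' @return Character vector of report lines, invisibly.
#' @export
run_report <- function(records, file = NULL) {
  n <- nrow(records)
  excl <- attr(records, "exclusions")
  lines <- c(
    "fire stop attribution report",
    sprintf("stops: %d", n),
    if (!is.null(excl)) sprintf("  excluded (%s): %d", names(excl), excl),
    sprintf("explained: %.1f%%", 100 * mean(records$explained)),
    "driver            flag%   share%")
  for (d in fs_drivers()) {
    lines <- c(lines, sprintf("  %-15s %6.1f %8.1f", d,
                              100 * mean(records[[d]]),
                              100 * sum(records[[paste0("contrib_", d)]]) / n))
  }
  lines <- c(lines, sprintf("  %-15s %6s %8.1f", "unknown", "-",
                            100 * sum(records$contrib_unknown) / n))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
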