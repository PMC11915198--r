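# Attribution module: combine weather and landscape test outcomes through
# the hierarchical decision tree and normalize per-stop contributions.

#' Apply the hierarchical decision tree to per-stop test outcomes
#'
#' The two fire-weather drivers (fuel moisture = VPD decline and/or soil
#' moisture increase; WFSI decline) and downslope are independent and pass
#' through unchanged. The five fuel-related landscape drivers are
#' interdependent (a river bank also shows up as a fuel-load and land-cover
#' change), so only the highest-priority significant one survives; the
#' default hierarchy is water > road > burn history > fuel load > land
#' cover, ordering hard barriers before subtler fuel changes. At most four
#' independent drivers can therefore be flagged at one stop.
#'
#' @param weather Weather attribution table from [attribute_weather_all()].
#' @param landscape Landscape attribution table from
#'   [attribute_landscape_all()].
#' @param hierarchy Character vector ordering the fuel-related landscape
#'   drivers (default `c("water", "road", "burn_history", "fuel_load",
#'   "land_cover")`).
#' @return A tibble of class `fs_records`: stop keys, one logical column per
#'   final driver flag, `n_flags`, `explained`, and normalized contribution
#'   columns `contrib_*` (each flagged driver gets `1 / n_flags`; an
#'   unexplained stop gets `contrib_unknown = 1`).
#' @export
apply_decision_tree <- function(weather, landscape,
                                hierarchy = fs_fuel_hierarchy_default()) {
  stopifnot(setequal(hierarchy, fs_fuel_hierarchy_default()))
  rec <- dplyr::left_join(weather, landscape,
                          by = c("stop_id", "fire_id"))
  fuel_cols <- paste0(hierarchy, "_flag")
  fuel_mat <- as.matrix(rec[, fuel_cols])
  fuel_mat[is.na(fuel_mat)] <- FALSE
  first_true <- apply(fuel_mat, 1, function(z) {
    k <- which(z)
    if (length(k)) k[1] else 0L
  })
  out <- tibble::tibble(
    stop_id = rec$stop_id,
    fire_id = rec$fire_id,
    fuel_moisture = isTRUE_v(rec$fuel_moisture),
    wfsi = isTRUE_v(rec$wfsi_flag),
    downslope = isTRUE_v(rec$downslope_flag)
  )
  for (k in seq_along(hierarchy)) {
    out[[hierarchy[k]]] <- first_true == k
  }
  out <- out[, c("stop_id", "fire_id", fs_drivers())]
  normalize_contributions(out)
}

isTRUE_v <- function(x) !is.na(x) & x

#' Normalize per-stop driver contributions
#'
#' Divides each flagged driver's contribution by the number of drivers
#' flagged at the stop, so that contributions sum to one per stop; a stop
#' with no flagged driver contributes one unit to the `unknown` category.
#'
#' @param records Tibble with one logical column per driver (see
#'   [fs_drivers()]); typically the output of [apply_decision_tree()].
#' @return The input with `n_flags`, `explained`, `contrib_<driver>` and
#'   `contrib_unknown` columns (re)computed; class `fs_records`.
#' @export
normalize_contributions <- function(records) {
  drv <- fs_drivers()
  flags <- as.matrix(records[, drv])
  flags[is.na(flags)] <- FALSE
  n_flags <- rowSums(flags)
  records$n_flags <- as.integer(n_flags)
  records$explained <- n_flags >= 1
  for (d in drv) {
    records[[paste0("contrib_", d)]] <-
      ifelse(n_flags > 0, flags[, d] / pmax(n_flags, 1), 0)
  }
  records$contrib_unknown <- as.numeric(n_flags == 0)
  class(records) <- unique(c("fs_records", class(records)))
  records
}

#' Run the full attribution pipeline over a table of stops
#'
#' Convenience driver: weather attribution, landscape attribution, decision
#' tree and contribution normalization, returning one record per stop with
#' stop coordinates and raw test outcomes retained. Stops excluded from one
#' analysis (incomplete weather window, undefined direction, one-sided
#' ellipse) can still be flagged by the other; `explained` reflects the
#' surviving flags only. Inputs must share the same coordinate frame.
#'
#' @param stops Stop tibble from [extract_fire_stops()].
#' @param scene,cube,stack Burn scene, weather cube, landscape stack.
#' @param alpha Significance level used by every test (default 0.01).
#' @param timing_window_days Breakpoint timing window in days relative to
#'   the burn day (default `c(-1, 2)`).
#' @param hierarchy Fuel-driver hierarchy (see [apply_decision_tree()]).
#' @param ... Further arguments passed to [attribute_weather_all()] and
#'   [attribute_landscape_all()] (`min_segment_frac`, `max_breaks`,
#'   `pooled`, `spacing`, `major_mult`, `minor_mult`, `grid_step`,
#'   `slope_threshold`, `recovery_years`, `correct_2x2`).
#' @return An `fs_records` tibble; attribute `exclusions` counts stops
#'   excluded from each analysis.
#' @export
attribute_all <- function(stops, scene, cube, stack, alpha = 0.01,
                          timing_window_days = c(-1, 2),
                          hierarchy = fs_fuel_hierarchy_default(), ...) {
  fs_check_crs(scene, cube, stack)
  dots <- list(...)
  take <- function(nms) dots[intersect(names(dots), nms)]
  if (nrow(stops) == 0) {
    d <- tibble::tibble(stop_id = integer(0), fire_id = integer(0))
    for (f in fs_drivers()) d[[f]] <- logical(0)
    return(normalize_contributions(d))
  }
  wx <- do.call(attribute_weather_all,
                c(list(stops, cube, alpha = alpha,
                       timing_window_days = timing_window_days),
                  take(c("min_segment_frac", "max_breaks", "pooled"))))
  ls <- do.call(attribute_landscape_all,
                c(list(stops, scene, stack, alpha = alpha),
                  take(c("spacing", "major_mult", "minor_mult", "grid_step",
                         "slope_threshold", "recovery_years", "correct_2x2"))))
  rec <- apply_decision_tree(wx, ls, hierarchy)
  rec <- dplyr::left_join(
    stops[, c("stop_id", "x", "y", "last_burn_date", "year")],
    rec, by = "stop_id")
  # retain raw outcomes for inspection (the pre-tree fuel-moisture flag is
  # identical to the final one, so it is dropped rather than suffixed)
  wx_raw <- wx[, setdiff(names(wx), c("fire_id", "fuel_moisture"))]
  rec <- dplyr::left_join(rec, wx_raw, by = "stop_id")
  rec <- dplyr::left_join(rec, ls[, setdiff(names(ls), "fire_id")], by = "stop_id")
  attr(rec, "exclusions") <- c(
    window_incomplete = sum(!wx$window_complete),
    direction_undefined = sum(!stops$direction_defined),
    landscape_untestable = sum(!ls$testable)
  )
  class(rec) <- unique(c("fs_records", class(rec)))
  rec
}
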