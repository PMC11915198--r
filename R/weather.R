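# Fire-weather module: VPD and WFSI series at each stop and the two-stage
# (split t-test, then breakpoint timing) attribution of weather drivers.

# Magnus/Tetens saturation vapor pressure over water (WMO constants), kPa
fs_esat <- function(t_c) 0.6112 * exp(17.62 * t_c / (243.12 + t_c))

# inverse of fs_esat (kPa -> deg C); valid for e > 0
fs_esat_inv <- function(e_kpa) {
  g <- log(e_kpa / 0.6112)
  243.12 * g / (17.62 - g)
}

#' Vapor pressure deficit from temperature and dewpoint
#'
#' VPD = e_s(T) - e_s(T_d) with the Magnus form
#' e_s(T) = 0.6112 exp(17.62 T / (243.12 + T)) kPa. Dewpoints above the air
#' temperature (supersaturation artifacts in reanalysis cells) are clamped
#' to the air temperature, so the result is non-negative. Non-finite inputs
#' propagate as NA.
#'
#' @param t2m 2 m air temperature, deg C.
#' @param d2m 2 m dewpoint temperature, deg C.
#' @return VPD in kPa, same shape as the inputs.
#' @export
compute_vpd <- function(t2m, d2m) {
  d <- pmin(d2m, t2m)
  out <- fs_esat(t2m) - fs_esat(d)
  out[!is.finite(t2m) | !is.finite(d2m)] <- NA_real_
  out
}

#' Wind fire spread index
#'
#' The projection of the 10 m wind vector (pointing where the air moves)
#' onto the stop's outward spread direction: positive when the wind pushes
#' the fire front toward the unburned side, negative when it opposes it,
#' with magnitude scaled by wind speed (range `[-speed, +speed]`).
#'
#' @param u,v Wind components (east, north), m/s.
#' @param dir_x,dir_y Outward unit direction of the stop.
#' @return WFSI in m/s; NA where the direction is undefined.
#' @export
compute_wfsi <- function(u, v, dir_x, dir_y) {
  u * dir_x + v * dir_y
}

#' Extract the 10-day hourly weather window of a fire stop
#'
#' Returns the 240 hourly values of VPD (kPa), WFSI (m/s) and surface soil
#' moisture from the coarse weather cell containing the stop (nearest-cell
#' lookup; points on a cell boundary go to the lower cell index), spanning
#' the 5 days before and including the last recorded burn date through the
#' 5 days after it. The split between halves falls after hour 120, the end
#' (UTC) of the burn day.
#'
#' @param cube A [weather_cube()].
#' @param stop One-row stop tibble (needs `x`, `y`, `last_burn_date`,
#'   `dir_x`, `dir_y`).
#' @return A tibble of class `fs_window` with columns `hour` (1-240), `doy`,
#'   `vpd`, `sm`, `wfsi` and attributes `split_index` (120), `burn_doy`,
#'   `complete`. If the window extends beyond the cube's time range the
#'   window is marked incomplete (`complete = FALSE`) and series are NA.
#' @export
extract_window <- function(cube, stop) {
  stopifnot(inherits(cube, "weather_cube"), nrow(stop) == 1)
  D <- stop$last_burn_date
  # absolute hour-of-year h of doy d: (d - 1) * 24 + 1 ... d * 24
  h0 <- (D - 5) * 24 + 1   # first hour of doy D - 4
  h1 <- (D + 5) * 24       # last hour of doy D + 5
  i0 <- h0 - (cube$start_doy - 1) * 24
  i1 <- h1 - (cube$start_doy - 1) * 24
  complete <- i0 >= 1 && i1 <= cube$n_hours
  hours <- 1:240
  doy <- (D - 5) + ((hours - 1) %/% 24) + 1
  if (!complete) {
    w <- tibble::tibble(hour = hours, doy = doy, vpd = NA_real_,
                        sm = NA_real_, wfsi = NA_real_)
  } else {
    rc <- fs_point_to_rc(stop$x, stop$y, cube$cell_size, cube$origin,
                         cube$n_rows, cube$n_cols)
    idx <- i0:i1
    t2m <- cube$t2m[cbind(idx, rc$row, rc$col)]
    d2m <- cube$d2m[cbind(idx, rc$row, rc$col)]
    u <- cube$u10[cbind(idx, rc$row, rc$col)]
    v <- cube$v10[cbind(idx, rc$row, rc$col)]
    sm <- cube$sm[cbind(idx, rc$row, rc$col)]
    wfsi <- if (isTRUE(stop$direction_defined)) {
      compute_wfsi(u, v, stop$dir_x, stop$dir_y)
    } else rep(NA_real_, 240)
    w <- tibble::tibble(hour = hours, doy = doy,
                        vpd = compute_vpd(t2m, d2m), sm = sm, wfsi = wfsi)
  }
  structure(w, class = c("fs_window", class(w)),
            split_index = 120L, burn_doy = D, complete = complete)
}

#' Two-sample split test on a weather window series
#'
#' Welch's unequal-variance two-sample t-test between the 120 hours before
#' and including the last recorded burn date and the 120 hours after it
#' (`pooled = TRUE` gives the pooled-variance form). The test passes iff
#' p < alpha and the mean changed in the stated direction.
#'
#' @param x Numeric series (length >= split_index + 1).
#' @param split_index Last index of the "before" half (default 120).
#' @param direction `"decline"` or `"increase"` (after vs before).
#' @param alpha Significance level (default 0.01).
#' @param pooled Use the pooled-variance Student form instead of Welch.
#' @return List with `t`, `p`, `pass`, `mean_before`, `mean_after`.
#' @export
split_ttest <- function(x, split_index = 120, direction = c("decline", "increase"),
                        alpha = 0.01, pooled = FALSE) {
  direction <- match.arg(direction)
  a <- x[seq_len(split_index)]
  b <- x[(split_index + 1):length(x)]
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) {
    return(list(t = NA_real_, p = NA_real_, pass = FALSE,
                mean_before = NA_real_, mean_after = NA_real_))
  }
  ma <- mean(a); mb <- mean(b)
  delta <- mb - ma
  dir_ok <- if (direction == "decline") delta < 0 else delta > 0
  if ((length(a) < 2 || sd(a) == 0) && (length(b) < 2 || sd(b) == 0)) {
    # degenerate: no within-half variance
    if (ma == mb) {
      return(list(t = 0, p = 1, pass = FALSE, mean_before = ma, mean_after = mb))
    }
    return(list(t = sign(delta) * Inf, p = .Machine$double.xmin,
                pass = dir_ok, mean_before = ma, mean_after = mb))
  }
  tt <- stats::t.test(b, a, var.equal = pooled)
  list(t = unname(tt$statistic), p = tt$p.value,
       pass = tt$p.value < alpha && dir_ok,
       mean_before = ma, mean_after = mb)
}

#' Attribute fire-weather drivers at one stop
#'
#' The two-stage attribution of the three fire-weather series in a stop's
#' 10-day window: for VPD (decline), soil moisture (increase) and WFSI
#' (decline), (1) a split t-test between the 5-day halves at level `alpha`;
#' (2) if it passes, multiple-breakpoint detection on the hourly series
#' ([detect_breakpoints()]); the driver is flagged iff some breakpoint's
#' entire confidence interval falls between the start of the day
#' `timing_window_days[1]` and the end of the day `timing_window_days[2]`
#' relative to the last recorded burn date. The fuel-moisture composite is
#' a significant VPD decline and/or soil-moisture increase.
#'
#' @param window An `fs_window` from [extract_window()].
#' @param alpha Significance level (default 0.01).
#' @param timing_window_days Integer length-2: days relative to the burn day
#'   that a breakpoint CI must fall within (default `c(-1, 2)`).
#' @param min_segment_frac,max_breaks Passed to [detect_breakpoints()].
#' @param pooled Passed to [split_ttest()].
#' @return One-row tibble with per-variable statistics, p-values, qualifying
#'   break hour and flags, plus `fuel_moisture`.
#' @export
attribute_weather <- function(window, alpha = 0.01, timing_window_days = c(-1, 2),
                              min_segment_frac = 0.15, max_breaks = 5,
                              pooled = FALSE) {
  split <- attr(window, "split_index") %||% 120L
  complete <- isTRUE(attr(window, "complete"))
  vars <- list(vpd = "decline", sm = "increase", wfsi = "decline")
  lo <- split - 24 + timing_window_days[1] * 24 + 1  # first hour of day tw[1]
  hi <- split + timing_window_days[2] * 24           # last hour of day tw[2]

  out <- list()
  for (v in names(vars)) {
    x <- window[[v]]
    res <- list(t = NA_real_, p = NA_real_, tpass = FALSE,
                break_hour = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                flag = FALSE)
    if (complete && sum(is.finite(x)) >= 0.9 * length(x)) {
      tt <- split_ttest(x, split, vars[[v]], alpha, pooled)
      res$t <- tt$t; res$p <- tt$p; res$tpass <- tt$pass
      if (tt$pass) {
        bp <- detect_breakpoints(x, min_segment_frac, max_breaks)
        if (bp$n_breaks > 0) {
          ok <- bp$ci_lo >= lo & bp$ci_hi <= hi
          if (any(ok)) {
            k <- which(ok)[1]
            res$break_hour <- bp$breaks[k]
            res$ci_lo <- bp$ci_lo[k]; res$ci_hi <- bp$ci_hi[k]
            res$flag <- TRUE
          }
        }
      }
    }
    names(res) <- paste0(v, "_", names(res))
    out <- c(out, res)
  }
  out$window_complete <- complete
  out$fuel_moisture <- out$vpd_flag || out$sm_flag
  tibble::as_tibble(out)
}

#' Attribute fire-weather drivers for a table of stops
#'
#' Maps [extract_window()] + [attribute_weather()] over a stop table. Stops
#' whose window extends beyond the cube (`window_complete = FALSE`) are
#' excluded from all weather flags; stops with undefined outward direction
#' are additionally excluded from the WFSI test.
#'
#' @param stops Stop tibble from [extract_fire_stops()].
#' @param cube A [weather_cube()].
#' @inheritParams attribute_weather
#' @return `stops` keys (`stop_id`, `fire_id`) joined with the per-stop
#'   weather attribution columns.
#' @export
attribute_weather_all <- function(stops, cube, alpha = 0.01,
                                  timing_window_days = c(-1, 2),
                                  min_segment_frac = 0.15, max_breaks = 5,
                                  pooled = FALSE) {
  res <- purrr::map(seq_len(nrow(stops)), function(i) {
    w <- extract_window(cube, stops[i, ])
    attribute_weather(w, alpha, timing_window_days,
                      min_segment_frac, max_breaks, pooled)
  })
  dplyr::bind_cols(stops[, c("stop_id", "fire_id")], dplyr::bind_rows(res))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
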