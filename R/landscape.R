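# Landscape module: perimeter-perpendicular ellipse sampling of the
# landscape layers and the burned-vs-unburned tests for each bottom-up
# driver.

#' Build the oriented sampling ellipse of a fire stop
#'
#' The ellipse is centered halfway between the stop pixel center (the first
#' unburned pixel) and the center of its nearest burned pixel, oriented
#' with its major axis along the stop's outward direction, with major axis
#' three times and minor axis one and a half times the stop spacing (900 m
#' and 450 m at 300 m spacing) so that roughly half the ellipse covers
#' burned and half unburned ground.
#'
#' @param stop One-row stop tibble (see [extract_fire_stops()]).
#' @param scene The [burn_scene()] the stop came from.
#' @param spacing Stop spacing in meters (default the scene pixel size).
#' @param major_mult,minor_mult Axis lengths as multiples of `spacing`
#'   (defaults 3 and 1.5).
#' @return An `fs_ellipse` object (center, semi-axes `a`, `b`, orientation),
#'   or `NULL` if the stop has no defined outward direction.
#' @export
build_ellipse <- function(stop, scene, spacing = NULL,
                          major_mult = 3, minor_mult = 1.5) {
  stopifnot(nrow(stop) == 1)
  if (!isTRUE(stop$direction_defined)) return(NULL)
  if (is.null(spacing)) spacing <- scene$pixel_size
  nb <- fs_pixel_center(stop$nb_row, stop$nb_col, scene$pixel_size, scene$origin)
  structure(list(
    center_x = (stop$x + nb$x) / 2,
    center_y = (stop$y + nb$y) / 2,
    a = major_mult * spacing / 2,   # semi-major, along the outward direction
    b = minor_mult * spacing / 2,   # semi-minor
    dir_x = stop$dir_x, dir_y = stop$dir_y
  ), class = "fs_ellipse")
}

#' Sample a landscape stack inside an oriented ellipse
#'
#' Lays a world-axis-aligned square lattice of `grid_step` cell centers
#' anchored at the ellipse center (points at center + (i + 1/2, j + 1/2)
#' times `grid_step`), keeps the points strictly inside the ellipse, and
#' looks up the burned flag (from the burn scene) and every landscape layer
#' at its native resolution (nearest cell) at each point.
#'
#' @param ellipse An `fs_ellipse` from [build_ellipse()].
#' @param scene The [burn_scene()].
#' @param stack A [landscape_stack()].
#' @param grid_step Sample spacing in meters (default 100).
#' @return Tibble with `x`, `y`, `u` (signed position along the outward
#'   axis), `w` (across-axis), `burned`, and one column per layer.
#' @export
sample_ellipse <- function(ellipse, scene, stack, grid_step = 100) {
  stopifnot(inherits(ellipse, "fs_ellipse"))
  K <- ceiling(ellipse$a / grid_step)
  off <- (seq(-K, K - 1) + 0.5) * grid_step
  g <- expand.grid(ox = off, oy = off)
  x <- ellipse$center_x + g$ox
  y <- ellipse$center_y + g$oy
  ex <- ellipse$dir_x; ey <- ellipse$dir_y
  u <- g$ox * ex + g$oy * ey
  w <- -g$ox * ey + g$oy * ex
  inside <- (u / ellipse$a)^2 + (w / ellipse$b)^2 < 1
  x <- x[inside]; y <- y[inside]; u <- u[inside]; w <- w[inside]
  out <- tibble::tibble(
    x = x, y = y, u = u, w = w,
    burned = fs_scene_at(scene, x, y) > 0
  )
  for (nm in names(stack$layers)) {
    out[[nm]] <- fs_layer_at(stack$layers[[nm]], x, y, stack$origin)
  }
  out
}

#' Continuous inside-to-outside driver test
#'
#' Welch two-sample t-test of a continuous layer between the burned (inside)
#' and unburned (outside) sample groups. The test passes iff p < alpha and
#' the change from inside to outside goes in the stated direction
#' (`"decrease"`: lower outside, as for tree cover and AGB; `"increase"`:
#' higher outside, as for the burn-history fuel-reduction fraction).
#'
#' @param sample An ellipse sample from [sample_ellipse()].
#' @param layer Name of the layer column to test.
#' @param direction `"decrease"` or `"increase"` (outside relative to inside).
#' @param alpha Significance level (default 0.01).
#' @param min_group Minimum samples per group (default 3).
#' @return List `t`, `p`, `pass`, `mean_in`, `mean_out`, `testable`.
#' @export
test_continuous <- function(sample, layer, direction = c("decrease", "increase"),
                            alpha = 0.01, min_group = 3) {
  direction <- match.arg(direction)
  xin <- sample[[layer]][sample$burned]
  xout <- sample[[layer]][!sample$burned]
  xin <- xin[is.finite(xin)]; xout <- xout[is.finite(xout)]
  base <- list(t = NA_real_, p = NA_real_, pass = FALSE,
               mean_in = NA_real_, mean_out = NA_real_, testable = FALSE)
  if (length(xin) < min_group || length(xout) < min_group) return(base)
  base$mean_in <- mean(xin); base$mean_out <- mean(xout)
  base$testable <- TRUE
  delta <- base$mean_out - base$mean_in
  dir_ok <- if (direction == "decrease") delta < 0 else delta > 0
  if (sd(xin) == 0 && sd(xout) == 0) {
    if (delta == 0) { base$t <- 0; base$p <- 1 }
    else { base$t <- sign(delta) * Inf; base$p <- .Machine$double.xmin
           base$pass <- dir_ok }
    return(base)
  }
  tt <- stats::t.test(xout, xin, var.equal = FALSE)
  base$t <- unname(tt$statistic); base$p <- tt$p.value
  base$pass <- tt$p.value < alpha && dir_ok
  base
}

#' Categorical inside-to-outside driver test
#'
#' Chi-squared test on the group (burned/unburned) by class contingency
#' table of a categorical or binary layer. Classes absent from both groups
#' are dropped. For 2x2 tables the Yates continuity correction is applied
#' by default and the test is skipped (no pass) when any expected count is
#' below 1. Direction gates: for presence layers (`mode = "presence"`,
#' roads and water) the presence fraction must be higher outside; for land
#' cover (`mode = "landcover"`) the class with the largest relative gain in
#' area share outside must differ from the modal class inside.
#'
#' @param sample An ellipse sample.
#' @param layer Layer column name.
#' @param alpha Significance level (default 0.01).
#' @param mode `"presence"` or `"landcover"`.
#' @param correct_2x2 Apply the Yates correction to 2x2 tables (default TRUE).
#' @return List `chisq`, `p`, `pass`, `direction_ok`, `testable`, `skipped`.
#' @export
test_categorical <- function(sample, layer, alpha = 0.01,
                             mode = c("presence", "landcover"),
                             correct_2x2 = TRUE) {
  mode <- match.arg(mode)
  base <- list(chisq = NA_real_, p = NA_real_, pass = FALSE,
               direction_ok = NA, testable = FALSE, skipped = FALSE)
  xin <- sample[[layer]][sample$burned]
  xout <- sample[[layer]][!sample$burned]
  xin <- xin[!is.na(xin)]; xout <- xout[!is.na(xout)]
  if (length(xin) == 0 || length(xout) == 0) return(base)
  base$testable <- TRUE
  classes <- sort(unique(c(xin, xout)))
  if (length(classes) < 2) { base$chisq <- 0; base$p <- 1; return(base) }
  tab <- rbind(inside = table(factor(xin, levels = classes)),
               outside = table(factor(xout, levels = classes)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    # chi-squared validity guard: with expected counts below one the
    # asymptotic test is badly anti-conservative at these sample sizes
    base$skipped <- TRUE
    return(base)
  }
  correct <- correct_2x2 && ncol(tab) == 2
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  base$chisq <- unname(ct$statistic); base$p <- ct$p.value
  if (mode == "presence") {
    base$direction_ok <- mean(xout > 0) > mean(xin > 0)
  } else {
    p_in <- tab["inside", ] / sum(tab["inside", ])
    p_out <- tab["outside", ] / sum(tab["outside", ])
    gain_class <- classes[which.max(p_out - p_in)]
    modal_in <- classes[which.max(tab["inside", ])]
    base$direction_ok <- gain_class != modal_in
  }
  base$pass <- is.finite(base$p) && base$p < alpha && isTRUE(base$direction_ok)
  base
}

#' Downslope test
#'
#' Tests for a significant decline in elevation from inside to outside the
#' perimeter (Welch t-test on the burned/unburned elevation groups) and
#' estimates the terrain slope along the outward axis as
#' `atan(delta mean elevation / delta mean along-axis position)` in degrees.
#' The stop is flagged only when the decline is significant at `alpha` AND
#' the slope is at or below `slope_threshold` (default -5 deg), the
#' experimental threshold below which downslope substantially limits
#' spread.
#'
#' @param sample An ellipse sample (needs `elevation` and `u` columns).
#' @param alpha Significance level (default 0.01).
#' @param slope_threshold Degrees (default -5).
#' @param min_group Minimum samples per group.
#' @return List `slope_deg`, `t`, `p`, `pass`, `testable`.
#' @export
test_downslope <- function(sample, alpha = 0.01, slope_threshold = -5,
                           min_group = 3) {
  ct <- test_continuous(sample, "elevation", "decrease", alpha, min_group)
  slope <- NA_real_
  if (ct$testable) {
    du <- mean(sample$u[!sample$burned]) - mean(sample$u[sample$burned])
    if (is.finite(du) && du != 0) {
      slope <- atan2(ct$mean_out - ct$mean_in, abs(du)) * 180 / pi
    }
  }
  list(slope_deg = slope, t = ct$t, p = ct$p,
       pass = isTRUE(ct$pass) && is.finite(slope) && slope <= slope_threshold,
       testable = ct$testable)
}

#' Fuel-load composite flag
#'
#' A decline in tree cover and/or aboveground biomass from inside to outside
#' the perimeter indicates a fuel-load limitation.
#'
#' @param tree_cover_pass,agb_pass Logical outcomes of the two continuous
#'   tests (NA counts as not passed).
#' @return Logical flag.
#' @export
combine_fuel_load <- function(tree_cover_pass, agb_pass) {
  isTRUE(tree_cover_pass) | isTRUE(agb_pass)
}

#' Attribute landscape drivers at one stop
#'
#' Builds the stop's oriented ellipse, samples all layers, and runs the full
#' battery: chi-squared presence tests for water and roads, t-tests for the
#' burn-history fuel-reduction fraction, tree cover and AGB (combined into
#' fuel load), the land-cover chi-squared test, and the downslope rule.
#' Flags here are raw test passes; the hierarchical decision tree is applied
#' later ([apply_decision_tree()]).
#'
#' @param stop One-row stop tibble.
#' @param scene,stack Burn scene and landscape stack.
#' @param alpha Significance level (default 0.01).
#' @param spacing,major_mult,minor_mult,grid_step Ellipse geometry
#'   parameters (see [build_ellipse()], [sample_ellipse()]).
#' @param slope_threshold Degrees for the downslope rule (default -5).
#' @param recovery_years Linear fuel-recovery horizon (years) mapping
#'   years-since-fire to a fuel-reduction fraction
#'   `clamp(1 - years / recovery_years, 0, 1)` (default 25).
#' @param correct_2x2 Yates correction for 2x2 tables.
#' @return One-row tibble of statistics, p-values and raw flags.
#' @export
attribute_landscape <- function(stop, scene, stack, alpha = 0.01,
                                spacing = NULL, major_mult = 3,
                                minor_mult = 1.5, grid_step = 100,
                                slope_threshold = -5, recovery_years = 25,
                                correct_2x2 = TRUE) {
  na_row <- tibble::tibble(
    testable = FALSE, n_burned = 0L, n_unburned = 0L,
    water_chisq = NA_real_, water_p = NA_real_, water_flag = FALSE,
    road_chisq = NA_real_, road_p = NA_real_, road_flag = FALSE,
    burn_history_t = NA_real_, burn_history_p = NA_real_, burn_history_flag = FALSE,
    tree_cover_t = NA_real_, tree_cover_p = NA_real_, tree_cover_flag = FALSE,
    agb_t = NA_real_, agb_p = NA_real_, agb_flag = FALSE,
    fuel_load_flag = FALSE,
    land_cover_chisq = NA_real_, land_cover_p = NA_real_, land_cover_flag = FALSE,
    downslope_slope = NA_real_, downslope_p = NA_real_, downslope_flag = FALSE)
  ell <- build_ellipse(stop, scene, spacing, major_mult, minor_mult)
  if (is.null(ell)) return(na_row)
  s <- sample_ellipse(ell, scene, stack, grid_step)
  n_in <- sum(s$burned); n_out <- sum(!s$burned)
  na_row$n_burned <- n_in; na_row$n_unburned <- n_out
  if (n_in == 0 || n_out == 0) return(na_row)
  na_row$testable <- TRUE

  if ("water" %in% names(s)) {
    w <- test_categorical(s, "water", alpha, "presence", correct_2x2)
    na_row$water_chisq <- w$chisq; na_row$water_p <- w$p
    na_row$water_flag <- isTRUE(w$pass)
  }
  if ("road" %in% names(s)) {
    r <- test_categorical(s, "road", alpha, "presence", correct_2x2)
    na_row$road_chisq <- r$chisq; na_row$road_p <- r$p
    na_row$road_flag <- isTRUE(r$pass)
  }
  if ("burn_history" %in% names(s)) {
    s$fuel_reduction <- pmin(pmax(1 - s$burn_history / recovery_years, 0), 1)
    b <- test_continuous(s, "fuel_reduction", "increase", alpha)
    na_row$burn_history_t <- b$t; na_row$burn_history_p <- b$p
    na_row$burn_history_flag <- isTRUE(b$pass)
  }
  tc_pass <- agb_pass <- FALSE
  if ("tree_cover" %in% names(s)) {
    tc <- test_continuous(s, "tree_cover", "decrease", alpha)
    na_row$tree_cover_t <- tc$t; na_row$tree_cover_p <- tc$p
    na_row$tree_cover_flag <- tc_pass <- isTRUE(tc$pass)
  }
  if ("agb" %in% names(s)) {
    ag <- test_continuous(s, "agb", "decrease", alpha)
    na_row$agb_t <- ag$t; na_row$agb_p <- ag$p
    na_row$agb_flag <- agb_pass <- isTRUE(ag$pass)
  }
  na_row$fuel_load_flag <- combine_fuel_load(tc_pass, agb_pass)
  if ("land_cover" %in% names(s)) {
    lc <- test_categorical(s, "land_cover", alpha, "landcover", correct_2x2)
    na_row$land_cover_chisq <- lc$chisq; na_row$land_cover_p <- lc$p
    na_row$land_cover_flag <- isTRUE(lc$pass)
  }
  if ("elevation" %in% names(s)) {
    d <- test_downslope(s, alpha, slope_threshold)
    na_row$downslope_slope <- d$slope_deg; na_row$downslope_p <- d$p
    na_row$downslope_flag <- isTRUE(d$pass)
  }
  na_row
}

#' Attribute landscape drivers for a table of stops
#'
#' @param stops Stop tibble from [extract_fire_stops()].
#' @inheritParams attribute_landscape
#' @return `stops` keys joined with per-stop landscape test columns.
#' @export
attribute_landscape_all <- function(stops, scene, stack, alpha = 0.01,
                                    spacing = NULL, major_mult = 3,
                                    minor_mult = 1.5, grid_step = 100,
                                    slope_threshold = -5, recovery_years = 25,
                                    correct_2x2 = TRUE) {
  res <- purrr::map(seq_len(nrow(stops)), function(i) {
    attribute_landscape(stops[i, ], scene, stack, alpha, spacing, major_mult,
                        minor_mult, grid_step, slope_threshold,
                        recovery_years, correct_2x2)
  })
  dplyr::bind_cols(stops[, c("stop_id", "fire_id")], dplyr::bind_rows(res))
}
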