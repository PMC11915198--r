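# Synthetic-data module: burn scenes, weather cubes and landscape stacks
# with planted, labeled cessation causes, so that every downstream stage of
# the attribution pipeline can be validated against a known ground truth.
#
# Fire growth is a raster flood fill: one Queen ring per day from an
# ignition pixel, clipped to a "burnable" mask derived from planted
# barriers, until the spread schedule ends. Weather is an hourly diurnal
# cycle plus white noise plus an additive step at the planted break; soil
# moisture is a mean-reverting AR(1) reflected at zero. Landscape causes
# are band features in side coordinates placed just outside the perimeter
# segment they stop.

fs_cause_kinds <- function() {
  c("vpd_drop", "sm_rise", "wfsi_drop", "water_edge", "road_edge",
    "burn_history_edge", "fuel_load_edge", "landcover_edge",
    "downslope_edge", "none")
}

#' Map a planted cause kind to the driver it should be recovered as
#' @param kind Cause kind (see [cause_spec()]).
#' @return Driver name, or NA for `"none"`.
#' @export
cause_to_driver <- function(kind) {
  map <- c(vpd_drop = "fuel_moisture", sm_rise = "fuel_moisture",
           wfsi_drop = "wfsi", water_edge = "water", road_edge = "road",
           burn_history_edge = "burn_history", fuel_load_edge = "fuel_load",
           landcover_edge = "land_cover", downslope_edge = "downslope",
           none = NA_character_)
  unname(map[kind])
}

#' Specify a planted cessation cause
#'
#' Weather causes (`vpd_drop`, `sm_rise`, `wfsi_drop`) are additive steps in
#' the weather series at the day boundary after the fire's last spread day
#' (the fire halts by schedule). Landscape causes are band features in the
#' coordinate perpendicular to one side of the fire, placed just outside
#' the perimeter segment they are meant to stop; they also act as barriers
#' to the flood-fill spread, so the fire genuinely halts against them.
#'
#' @param kind One of `r paste(fs_cause_kinds(), collapse = ", ")`.
#' @param size Effect size. Defaults by kind: `vpd_drop` 1 kPa, `sm_rise`
#'   0.08 m3/m3, `wfsi_drop` 6 m/s (the wind swings from +size/2 to
#'   -size/2 along the side normal), `burn_history_edge` 3 years since
#'   fire outside, `downslope_edge` -10 degrees, `landcover_edge` class 2.
#' @param side Which flank the feature blocks: `"E"`, `"W"`, `"N"`, `"S"`.
#' @param distance_px Distance (pixels) from the ignition to the first
#'   blocked pixel (default 5). Must be >= 1.
#' @param width_m,offset_m Band width and offset beyond the halt boundary,
#'   meters. Defaults by kind: water 600/0, road 200/100, others 900/0.
#' @param values For `fuel_load_edge`, a named list overriding the outside
#'   values (`tree_cover`, default 26 percent; `agb`, default 23 Mg/ha).
#' @param fire Index of the fire the cause attaches to (default 1).
#' @return A `cause_spec` list.
#' @export
cause_spec <- function(kind, size = NULL, side = "E", distance_px = 5,
                       width_m = NULL, offset_m = NULL, values = NULL,
                       fire = 1L) {
  kind <- match.arg(kind, fs_cause_kinds())
  side <- match.arg(side, c("E", "W", "N", "S"))
  size <- size %||% switch(kind,
    vpd_drop = 1.0, sm_rise = 0.08, wfsi_drop = 6,
    burn_history_edge = 3, downslope_edge = -10, landcover_edge = 2, 0)
  if (!is.finite(size)) stop("cause effect size must be finite")
  width_m <- width_m %||% switch(kind,
    water_edge = 600, road_edge = 200, 900)
  offset_m <- offset_m %||% switch(kind, road_edge = 100, 0)
  if (kind == "fuel_load_edge") {
    values <- utils::modifyList(list(tree_cover = 26, agb = 23), values %||% list())
  }
  structure(list(kind = kind, size = size, side = side,
                 distance_px = as.integer(distance_px),
                 width_m = width_m, offset_m = offset_m,
                 values = values, fire = as.integer(fire)),
            class = "cause_spec")
}

#' Specify one synthetic fire
#'
#' @param ignition Integer `c(row, col)` of the ignition pixel, or `NULL`
#'   to auto-place.
#' @param start_doy Day-of-year of ignition.
#' @param n_days Number of spread days (the fire's Chebyshev radius is
#'   `n_days - 1` pixels where unobstructed).
#' @return A `fire_spec` list.
#' @export
fire_spec <- function(ignition = NULL, start_doy = 180, n_days = 8) {
  structure(list(ignition = ignition, start_doy = as.integer(start_doy),
                 n_days = as.integer(n_days)), class = "fire_spec")
}

#' Configure a synthetic scenario
#'
#' Defaults describe a 14.4 x 14.4 km tile of boreal forest at the burned
#' area product's 300 m resolution: one mid-summer fire, a mean mid-season
#' VPD of 1.2 kPa with a 0.4 kPa diurnal amplitude over a 20 +/- 6 deg C
#' day, 0.25 m3/m3 surface soil moisture, 45 percent tree cover and
#' 48 Mg/ha aboveground biomass (matching the magnitudes reported for
#' Siberian larch forest), and long-unburned fuels.
#'
#' @param grid_shape `c(rows, cols)` of the 300 m burn grid.
#' @param pixel_size Burn-grid pixel size, meters.
#' @param fires List of [fire_spec()]; if `NULL`, `n_fires` fires of
#'   `fire_size_range` spread days are auto-placed on a block grid with
#'   jittered ignitions and start days.
#' @param n_fires,fire_size_range,burn_start_doy Auto-placement parameters.
#' @param planted_causes List of [cause_spec()].
#' @param noise Named list of noise levels (sd) per realized quantity:
#'   `vpd` (kPa), `sm` (m3/m3), `wind` (m/s), `tree_cover` (percent),
#'   `agb` (Mg/ha), `elevation` (m), `burn_history` (years), and sprinkle
#'   probabilities `water_p`, `road_p`, `land_cover_p`.
#' @param baseline Named list of baseline levels (see defaults).
#' @param sm_phi AR(1) coefficient of the soil-moisture process in
#'   [generate_scenario()] (default 0.5; [null_scenario()] uses white
#'   noise).
#' @param weather_cell_px Coarse weather cell size in burn pixels
#'   (default 10, i.e. 3 km cells).
#' @param layer_res Named numeric: native resolution (m) per landscape
#'   layer.
#' @param year Scene year.
#' @param seed Integer seed; identical configs give byte-identical outputs.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(grid_shape = c(48, 48), pixel_size = 300,
                            fires = NULL, n_fires = 1,
                            fire_size_range = c(6, 9), burn_start_doy = 180,
                            planted_causes = list(),
                            noise = list(), baseline = list(),
                            sm_phi = 0.5, weather_cell_px = 10,
                            layer_res = NULL, year = 2020L, seed = 1L) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 4), pixel_size > 0)
  noise <- utils::modifyList(list(
    vpd = 0.15, sm = 0.02, wind = 1.0, tree_cover = 5, agb = 8,
    elevation = 2, burn_history = 2, water_p = 0, road_p = 0,
    land_cover_p = 0), noise)
  baseline <- utils::modifyList(list(
    t2m_mean = 20, t2m_amp = 6, vpd_mean = 1.2, vpd_amp = 0.4,
    sm_mean = 0.25, u = 0, v = 0, tree_cover = 45, agb = 48,
    elevation = 200, land_class = 1, years_since_fire = 60), baseline)
  layer_res <- layer_res %||% c(tree_cover = 30, agb = 100, land_cover = 300,
                                burn_history = 300, elevation = 30,
                                road = 30, water = 30)
  if (length(planted_causes) && inherits(planted_causes, "cause_spec")) {
    planted_causes <- list(planted_causes)
  }
  for (cs in planted_causes) stopifnot(inherits(cs, "cause_spec"))
  if (!is.null(fires) && inherits(fires, "fire_spec")) fires <- list(fires)
  structure(list(
    grid_shape = as.integer(grid_shape), pixel_size = pixel_size,
    fires = fires, n_fires = as.integer(n_fires),
    fire_size_range = as.integer(fire_size_range),
    burn_start_doy = as.integer(burn_start_doy),
    planted_causes = planted_causes, noise = noise, baseline = baseline,
    sm_phi = sm_phi, weather_cell_px = as.integer(weather_cell_px),
    layer_res = layer_res, year = as.integer(year), seed = as.integer(seed)
  ), class = "scenario_config")
}

fs_side_normal <- function(side) {
  switch(side, E = c(1, 0), W = c(-1, 0), N = c(0, 1), S = c(0, -1))
}

# signed side coordinate: grows toward the named side
fs_side_coord <- function(side, x, y) {
  switch(side, E = x, W = -x, N = y, S = -y)
}

#' Generate a synthetic scenario
#'
#' Realizes the scenario described by a [scenario_config()]: a burn scene
#' whose fires grow outward one Queen ring per day from their ignition
#' pixels until they meet a planted barrier or their spread schedule ends;
#' an hourly weather cube with planted step changes at the day boundary
#' after each fire's halt day; a landscape stack with planted edge features
#' just outside the perimeter segments they stop; and a ground-truth table
#' labeling every stop with its (possibly empty) set of true causes.
#'
#' Truth labels attach to the stops a cause actually stopped: for weather
#' causes, stops whose last burn date is the fire's halt day (WFSI
#' additionally requires the stop to face the planted side); for landscape
#' causes, stops that face the planted side and whose outward axis meets
#' the feature within one minor-axis length (450 m).
#'
#' @param config A [scenario_config()].
#' @param .sm_model Internal: `"ar1"` (default) or `"white"` (used by
#'   [null_scenario()]).
#' @return List of class `fs_scenario`: `scene` ([burn_scene()]), `cube`
#'   ([weather_cube()]), `stack` ([landscape_stack()]), `stops` (tibble),
#'   `truth` (tibble with list-column `causes`), `cause_table` (one row per
#'   planted cause with its magnitude and halt day).
#' @export
generate_scenario <- function(config, .sm_model = c("ar1", "white")) {
  stopifnot(inherits(config, "scenario_config"))
  .sm_model <- match.arg(.sm_model)
  withr::with_seed(config$seed, fs_realize_scenario(config, .sm_model))
}

#' Generate a null scenario
#'
#' The calibration harness: no planted causes, fires halt by fiat when
#' their spread schedule ends, every weather series is stationary (diurnal
#' cycle plus white noise) and every landscape layer homogeneous up to
#' noise. Used to measure false-flag rates of the attribution tests.
#'
#' @param config A [scenario_config()] with `planted_causes` empty.
#' @inherit generate_scenario return
#' @export
null_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (length(config$planted_causes) > 0) {
    stop("null_scenario requires an empty planted_causes list")
  }
  generate_scenario(config, .sm_model = "white")
}

# ---- internals -------------------------------------------------------------

fs_resolve_fires <- function(config) {
  if (!is.null(config$fires)) {
    fires <- config$fires
    for (k in seq_along(fires)) {
      if (is.null(fires[[k]]$ignition)) {
        stop("explicit fire_spec needs an ignition pixel")
      }
    }
    return(fires)
  }
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  nb <- ceiling(sqrt(config$n_fires))
  bh <- floor(nr / nb); bw <- floor(nc / nb)
  fires <- vector("list", config$n_fires)
  cells <- utils::head(expand.grid(bi = seq_len(nb), bj = seq_len(nb)),
                       config$n_fires)
  for (k in seq_len(config$n_fires)) {
    jit <- max(1, floor(min(bh, bw) / 6))
    r <- (cells$bi[k] - 1) * bh + floor(bh / 2) +
      sample.int(2 * jit + 1, 1) - jit - 1
    c <- (cells$bj[k] - 1) * bw + floor(bw / 2) +
      sample.int(2 * jit + 1, 1) - jit - 1
    nd <- sample(seq(config$fire_size_range[1], config$fire_size_range[2]), 1)
    sd0 <- config$burn_start_doy + sample.int(11, 1) - 1
    fires[[k]] <- fire_spec(c(max(1, min(nr, r)), max(1, min(nc, c))),
                            start_doy = sd0, n_days = nd)
  }
  fires
}

fs_realize_scenario <- function(config, sm_model) {
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  px <- config$pixel_size
  origin <- c(0, nr * px)
  fires <- fs_resolve_fires(config)
  causes <- config$planted_causes
  for (cs in causes) {
    if (cs$fire < 1 || cs$fire > length(fires)) {
      stop("cause_spec refers to fire ", cs$fire, " but only ",
           length(fires), " fire(s) are defined")
    }
  }

  # --- barrier masks + halt boundaries -------------------------------------
  cx <- origin[1] + (col(matrix(0, nr, nc)) - 0.5) * px
  cy <- origin[2] - (row(matrix(0, nr, nc)) - 0.5) * px
  boundary <- list()   # per cause: side coordinate of the halt boundary
  burnable <- rep(list(matrix(TRUE, nr, nc)), length(fires))
  for (ci in seq_along(causes)) {
    cs <- causes[[ci]]
    if (cs$kind %in% c("vpd_drop", "sm_rise", "wfsi_drop", "none")) {
      boundary[[ci]] <- NA_real_
      next
    }
    ig <- fires[[cs$fire]]$ignition
    ig_xy <- fs_pixel_center(ig[1], ig[2], px, origin)
    b <- fs_side_coord(cs$side, ig_xy$x, ig_xy$y) + (cs$distance_px - 0.5) * px
    boundary[[ci]] <- b
    s <- fs_side_coord(cs$side, cx, cy)
    blocked <- s >= b
    if (blocked[ig[1], ig[2]]) {
      stop("infeasible geometry: planted ", cs$kind,
           " barrier covers the fire seed at (", ig[1], ", ", ig[2], ")")
    }
    burnable[[cs$fire]] <- burnable[[cs$fire]] & !blocked
  }

  # --- fire growth (flood fill, one Queen ring per day) --------------------
  dob <- matrix(0L, nr, nc)
  fid <- matrix(0L, nr, nc)
  halt_doy <- integer(length(fires))
  ord <- order(vapply(fires, function(f) f$start_doy, integer(1)))
  for (k in ord) {
    f <- fires[[k]]
    ig <- f$ignition
    if (dob[ig[1], ig[2]] > 0) next  # seed already burned by another fire
    if (!burnable[[k]][ig[1], ig[2]]) {
      stop("infeasible geometry: barrier covers the fire seed")
    }
    front <- matrix(c(ig[1], ig[2]), ncol = 2)
    dob[ig[1], ig[2]] <- f$start_doy
    fid[ig[1], ig[2]] <- k
    day <- f$start_doy
    for (d in seq_len(f$n_days - 1)) {
      if (nrow(front) == 0) break
      newc <- NULL
      for (q in 1:8) {
        r2 <- front[, 1] + fs_queen[q, 1]
        c2 <- front[, 2] + fs_queen[q, 2]
        ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
        r2 <- r2[ok]; c2 <- c2[ok]
        if (!length(r2)) next
        free <- dob[cbind(r2, c2)] == 0 & burnable[[k]][cbind(r2, c2)]
        if (any(free)) newc <- rbind(newc, cbind(r2[free], c2[free]))
      }
      if (is.null(newc) || nrow(newc) == 0) break
      newc <- unique(newc)
      day <- f$start_doy + d
      dob[newc] <- day
      fid[newc] <- k
      front <- newc
    }
    halt_doy[k] <- max(dob[fid == k])
  }

  scene <- burn_scene(dob, fid, px, origin, year = config$year)
  stops <- extract_fire_stops(scene)

  # --- landscape stack -----------------------------------------------------
  res <- config$layer_res
  nz <- config$noise; bs <- config$baseline
  mk <- function(layer) {
    r <- res[[layer]]
    dims <- c(ceiling(nr * px / r), ceiling(nc * px / r))
    list(res = r, nrow = dims[1], ncol = dims[2],
         x = origin[1] + (col(matrix(0, dims[1], dims[2])) - 0.5) * r,
         y = origin[2] - (row(matrix(0, dims[1], dims[2])) - 0.5) * r)
  }
  geo <- lapply(stats::setNames(nm = names(res)), mk)
  layers <- list(
    tree_cover = pmin(pmax(bs$tree_cover +
      matrix(rnorm(geo$tree_cover$nrow * geo$tree_cover$ncol, 0, nz$tree_cover),
             geo$tree_cover$nrow), 0), 100),
    agb = pmax(bs$agb +
      matrix(rnorm(geo$agb$nrow * geo$agb$ncol, 0, nz$agb), geo$agb$nrow), 0),
    land_cover = matrix(bs$land_class, geo$land_cover$nrow, geo$land_cover$ncol),
    burn_history = pmax(bs$years_since_fire +
      matrix(rnorm(geo$burn_history$nrow * geo$burn_history$ncol, 0,
                   nz$burn_history), geo$burn_history$nrow), 0),
    elevation = bs$elevation +
      matrix(rnorm(geo$elevation$nrow * geo$elevation$ncol, 0, nz$elevation),
             geo$elevation$nrow),
    road = matrix(0, geo$road$nrow, geo$road$ncol),
    water = matrix(0, geo$water$nrow, geo$water$ncol)
  )
  if (nz$land_cover_p > 0) {
    n <- length(layers$land_cover)
    flip <- runif(n) < nz$land_cover_p
    layers$land_cover[flip] <- sample(setdiff(1:4, bs$land_class), sum(flip),
                                      replace = TRUE)
  }
  if (nz$road_p > 0) {
    layers$road[runif(length(layers$road)) < nz$road_p] <- 1
  }
  if (nz$water_p > 0) {
    layers$water[runif(length(layers$water)) < nz$water_p] <- 1
  }

  paint <- function(layer, mask, value) {
    m <- layers[[layer]]
    m[mask] <- value
    layers[[layer]] <<- m
  }
  for (ci in seq_along(causes)) {
    cs <- causes[[ci]]
    if (cs$kind %in% c("vpd_drop", "sm_rise", "wfsi_drop", "none")) next
    b <- boundary[[ci]]
    band <- function(layer, from = b + cs$offset_m,
                     to = b + cs$offset_m + cs$width_m) {
      s <- fs_side_coord(cs$side, geo[[layer]]$x, geo[[layer]]$y)
      s >= from & s < to
    }
    if (cs$kind == "water_edge") {
      paint("water", band("water"), 1)
      paint("tree_cover", band("tree_cover"), 0)
      paint("agb", band("agb"), 0)
      paint("land_cover", band("land_cover"), 9)  # water body class
    } else if (cs$kind == "road_edge") {
      paint("road", band("road"), 1)
    } else if (cs$kind == "burn_history_edge") {
      m <- band("burn_history")
      layers$burn_history[m] <- pmax(
        cs$size + rnorm(sum(m), 0, nz$burn_history), 0)
    } else if (cs$kind == "fuel_load_edge") {
      m <- band("tree_cover")
      layers$tree_cover[m] <- pmin(pmax(
        cs$values$tree_cover + rnorm(sum(m), 0, nz$tree_cover), 0), 100)
      m <- band("agb")
      layers$agb[m] <- pmax(cs$values$agb + rnorm(sum(m), 0, nz$agb), 0)
    } else if (cs$kind == "landcover_edge") {
      paint("land_cover", band("land_cover"), cs$size)
    } else if (cs$kind == "downslope_edge") {
      ramp_back <- 450
      s <- fs_side_coord(cs$side, geo$elevation$x, geo$elevation$y)
      m <- s >= b - ramp_back
      drop <- tan(abs(cs$size) * pi / 180) * (s[m] - (b - ramp_back))
      layers$elevation[m] <- layers$elevation[m] - drop
    }
  }
  stack <- landscape_stack(
    lapply(stats::setNames(nm = names(layers)), function(nm) {
      kind <- switch(nm, land_cover = "categorical",
                     road = , water = "binary", "continuous")
      landscape_layer(layers[[nm]], res[[nm]], kind)
    }), origin = origin)

  # --- weather cube --------------------------------------------------------
  wpx <- config$weather_cell_px
  wr <- ceiling(nr / wpx); wc <- ceiling(nc / wpx)
  cell_size <- wpx * px
  starts <- vapply(fires, function(f) f$start_doy, integer(1))
  doy0 <- min(starts) - 6
  doy1 <- max(c(halt_doy, starts)) + 6
  Th <- (doy1 - doy0 + 1) * 24
  hod <- ((seq_len(Th) - 1) %% 24)  # hour of day 0..23
  diurnal <- sin(2 * pi * (hod - 15) / 24)
  t2m <- array(0, c(Th, wr, wc)); vpd <- array(0, c(Th, wr, wc))
  u10 <- array(0, c(Th, wr, wc)); v10 <- array(0, c(Th, wr, wc))
  smx <- array(0, c(Th, wr, wc))
  for (i in seq_len(wr)) for (j in seq_len(wc)) {
    t2m[, i, j] <- bs$t2m_mean + bs$t2m_amp * diurnal
    vpd[, i, j] <- bs$vpd_mean + bs$vpd_amp * diurnal + rnorm(Th, 0, nz$vpd)
    u10[, i, j] <- bs$u + rnorm(Th, 0, nz$wind)
    v10[, i, j] <- bs$v + rnorm(Th, 0, nz$wind)
    if (sm_model == "white") {
      smx[, i, j] <- bs$sm_mean + rnorm(Th, 0, nz$sm)
    } else {
      e <- rnorm(Th, 0, nz$sm)
      z <- numeric(Th)
      z[1] <- bs$sm_mean + e[1] / sqrt(1 - config$sm_phi^2)
      for (t in 2:Th) {
        z[t] <- bs$sm_mean + config$sm_phi * (z[t - 1] - bs$sm_mean) + e[t]
      }
      smx[, i, j] <- z
    }
  }
  # planted weather steps: applied to the cells overlapping the fire's
  # bounding box (plus one cell margin), from the first hour after the halt
  # day, so a stop dated to the halt day sees the break at window hour 120
  for (ci in seq_along(causes)) {
    cs <- causes[[ci]]
    if (!cs$kind %in% c("vpd_drop", "sm_rise", "wfsi_drop")) next
    k <- cs$fire
    idx <- which(fid == k, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    ri <- max(1, floor((min(idx[, 1]) - 1) / wpx)):(min(wr, ceiling(max(idx[, 1]) / wpx) + 1))
    cj <- max(1, floor((min(idx[, 2]) - 1) / wpx)):(min(wc, ceiling(max(idx[, 2]) / wpx) + 1))
    ri <- ri[ri >= 1]; cj <- cj[cj >= 1]
    h_step <- halt_doy[k] * 24 + 1 - (doy0 - 1) * 24  # first hour after halt day
    if (h_step < 1 || h_step > Th) next
    after <- h_step:Th
    nrm <- fs_side_normal(cs$side)
    for (i in ri) for (j in cj) {
      if (cs$kind == "vpd_drop") {
        vpd[after, i, j] <- vpd[after, i, j] - cs$size
      } else if (cs$kind == "sm_rise") {
        smx[after, i, j] <- smx[after, i, j] + cs$size
      } else {
        u10[, i, j] <- u10[, i, j] + nrm[1] * cs$size / 2
        v10[, i, j] <- v10[, i, j] + nrm[2] * cs$size / 2
        u10[after, i, j] <- u10[after, i, j] - nrm[1] * cs$size
        v10[after, i, j] <- v10[after, i, j] - nrm[2] * cs$size
      }
    }
  }
  vpd <- pmin(pmax(vpd, 0.01), fs_esat(t2m) - 0.05)
  d2m <- fs_esat_inv(fs_esat(t2m) - vpd)
  smx <- pmin(pmax(smx, 0.005), 0.995)
  cube <- weather_cube(t2m, d2m, u10, v10, smx, start_doy = doy0,
                       cell_size = cell_size, origin = origin)

  # --- ground truth --------------------------------------------------------
  truth_causes <- vector("list", nrow(stops))
  for (i in seq_len(nrow(stops))) truth_causes[[i]] <- character(0)
  for (ci in seq_along(causes)) {
    cs <- causes[[ci]]
    if (cs$kind == "none") next
    k <- cs$fire
    sel <- stops$fire_id == k
    if (cs$kind %in% c("vpd_drop", "sm_rise")) {
      hit <- sel & stops$last_burn_date == halt_doy[k]
    } else {
      nrm <- fs_side_normal(cs$side)
      facing <- stops$direction_defined &
        (stops$dir_x * nrm[1] + stops$dir_y * nrm[2]) > 0.75
      if (cs$kind == "wfsi_drop") {
        hit <- sel & facing & stops$last_burn_date == halt_doy[k]
      } else {
        b <- boundary[[ci]]
        from <- b + cs$offset_m
        to <- b + cs$offset_m + cs$width_m
        if (cs$kind == "downslope_edge") { from <- b - 450; to <- Inf }
        probe_hit <- rep(FALSE, nrow(stops))
        for (t in c(0, 150, 300, 450)) {
          sx <- stops$x + t * stops$dir_x
          sy <- stops$y + t * stops$dir_y
          s <- fs_side_coord(cs$side, sx, sy)
          probe_hit <- probe_hit | (s >= from & s < to)
        }
        hit <- sel & facing & probe_hit
      }
    }
    for (i in which(hit)) {
      truth_causes[[i]] <- union(truth_causes[[i]], cs$kind)
    }
  }
  truth <- stops[, c("stop_id", "fire_id", "row", "col", "x", "y",
                     "last_burn_date")]
  truth$causes <- truth_causes
  cause_table <- if (length(causes)) {
    tibble::tibble(
      cause = seq_along(causes),
      kind = vapply(causes, `[[`, character(1), "kind"),
      fire = vapply(causes, `[[`, integer(1), "fire"),
      size = vapply(causes, `[[`, numeric(1), "size"),
      side = vapply(causes, `[[`, character(1), "side"),
      halt_doy = halt_doy[vapply(causes, `[[`, integer(1), "fire")]
    )
  } else {
    tibble::tibble(cause = integer(0), kind = character(0), fire = integer(0),
                   size = numeric(0), side = character(0), halt_doy = integer(0))
  }

  structure(list(scene = scene, cube = cube, stack = stack, stops = stops,
                 truth = truth, cause_table = cause_table,
                 halt_doy = halt_doy, config = config),
            class = "fs_scenario")
}

#' @export
print.fs_scenario <- function(x, ...) {
  cat(sprintf("<fs_scenario> %d fire(s), %d stops, %d planted cause(s)\n",
              length(x$halt_doy), nrow(x$stops), nrow(x$cause_table)))
  invisible(x)
}
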