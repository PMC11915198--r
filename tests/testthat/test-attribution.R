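mk_weather_row <- function(stop_id, fuel_moisture = FALSE, wfsi = FALSE) {
  tibble::tibble(stop_id = stop_id, fire_id = 1L,
                 vpd_flag = fuel_moisture, sm_flag = FALSE,
                 wfsi_flag = wfsi, window_complete = TRUE,
                 fuel_moisture = fuel_moisture)
}

mk_landscape_row <- function(stop_id, water = FALSE, road = FALSE,
                             burn_history = FALSE, fuel_load = FALSE,
                             land_cover = FALSE, downslope = FALSE) {
  tibble::tibble(stop_id = stop_id, fire_id = 1L, testable = TRUE,
                 water_flag = water, road_flag = road,
                 burn_history_flag = burn_history,
                 fuel_load_flag = fuel_load, land_cover_flag = land_cover,
                 downslope_flag = downslope)
}

test_that("the decision tree keeps one fuel driver and caps flags at four", {
  # everything significant at once: water wins among the fuel-related
  # drivers, so flags = {fuel_moisture, wfsi, downslope, water}
  w <- mk_weather_row(1L, fuel_moisture = TRUE, wfsi = TRUE)
  l <- mk_landscape_row(1L, water = TRUE, road = TRUE, fuel_load = TRUE,
                        land_cover = TRUE, downslope = TRUE)
  r <- apply_decision_tree(w, l)
  expect_true(all(unlist(r[, c("fuel_moisture", "wfsi", "downslope", "water")])))
  expect_false(any(unlist(r[, c("road", "burn_history", "fuel_load",
                                "land_cover")])))
  expect_equal(r$n_flags, 4)
  expect_equal(r$contrib_water, 0.25)

  # burn history beats land cover in the hierarchy
  r2 <- apply_decision_tree(mk_weather_row(1L),
                            mk_landscape_row(1L, burn_history = TRUE,
                                             land_cover = TRUE))
  expect_true(r2$burn_history); expect_false(r2$land_cover)
  expect_equal(r2$n_flags, 1)

  # nothing significant: unexplained
  r3 <- apply_decision_tree(mk_weather_row(1L), mk_landscape_row(1L))
  expect_false(r3$explained)
  expect_equal(r3$contrib_unknown, 1)
})

test_that("the tree is idempotent and never keeps two fuel drivers", {
  withr::with_seed(13, {
    n <- 200
    w <- tibble::tibble(stop_id = 1:n, fire_id = 1L,
                        vpd_flag = runif(n) < 0.3, sm_flag = runif(n) < 0.3,
                        wfsi_flag = runif(n) < 0.3, window_complete = TRUE)
    w$fuel_moisture <- w$vpd_flag | w$sm_flag
    l <- tibble::tibble(stop_id = 1:n, fire_id = 1L, testable = TRUE,
                        water_flag = runif(n) < 0.2,
                        road_flag = runif(n) < 0.2,
                        burn_history_flag = runif(n) < 0.2,
                        fuel_load_flag = runif(n) < 0.2,
                        land_cover_flag = runif(n) < 0.2,
                        downslope_flag = runif(n) < 0.2)
    r <- apply_decision_tree(w, l)
    fuel <- c("water", "road", "burn_history", "fuel_load", "land_cover")
    expect_true(all(rowSums(as.matrix(r[, fuel])) <= 1))
    expect_true(all(r$n_flags <= 4))
    # applying the tree to its own output changes nothing
    l2 <- l
    for (d in fuel) l2[[paste0(d, "_flag")]] <- r[[d]]
    r2 <- apply_decision_tree(w, l2)
    expect_equal(r2[, c(fs_drivers(), "n_flags")],
                 r[, c(fs_drivers(), "n_flags")])
    # contributions sum to exactly one per stop (or one unit of unknown)
    tot <- rowSums(as.matrix(r[, paste0("contrib_", fs_drivers())])) +
      r$contrib_unknown
    expect_equal(tot, rep(1, n))
    expect_equal(sum(as.matrix(r[, grep("^contrib_", names(r))])), n)
  })
})

test_that("contribution normalization divides equally among flags", {
  d <- tibble::tibble(stop_id = 1:3, fire_id = 1L)
  for (f in fs_drivers()) d[[f]] <- FALSE
  d$fuel_moisture[1] <- TRUE; d$water[1] <- TRUE
  d$fuel_moisture[2] <- TRUE; d$wfsi[2] <- TRUE
  d$downslope[2] <- TRUE; d$road[2] <- TRUE
  r <- normalize_contributions(d)
  expect_equal(r$contrib_fuel_moisture, c(0.5, 0.25, 0))
  expect_equal(r$contrib_road, c(0, 0.25, 0))
  expect_equal(r$contrib_unknown, c(0, 0, 1))
  expect_equal(r$explained, c(TRUE, TRUE, FALSE))
})

test_that("the full pipeline recovers a planted water edge plus VPD drop", {
  cfg <- scenario_config(
    seed = 33, grid_shape = c(40, 40),
    fires = fire_spec(c(20, 18), n_days = 9),
    planted_causes = list(cause_spec("water_edge", distance_px = 5),
                          cause_spec("vpd_drop")))
  sc <- generate_scenario(cfg)
  rec <- attribute_all(sc$stops, sc$scene, sc$cube, sc$stack)
  expect_equal(nrow(rec), nrow(sc$stops))

  truth_has <- function(kind) {
    vapply(sc$truth$causes, function(z) kind %in% z, logical(1))
  }
  water_stops <- rec[rec$stop_id %in% sc$truth$stop_id[truth_has("water_edge")], ]
  vpd_stops <- rec[rec$stop_id %in% sc$truth$stop_id[truth_has("vpd_drop")], ]
  expect_gt(nrow(water_stops), 0)
  expect_gt(nrow(vpd_stops), 0)
  expect_gte(mean(water_stops$water), 0.9)
  expect_gte(mean(vpd_stops$fuel_moisture), 0.9)
  # the water band has no trees: the raw fuel tests co-trigger, the
  # hierarchy must suppress them at every water-flagged stop
  expect_false(any(water_stops$water & (water_stops$fuel_load |
                                          water_stops$land_cover)))
  # determinism of the whole pipeline
  rec2 <- attribute_all(sc$stops, sc$scene, sc$cube, sc$stack)
  expect_identical(as.data.frame(rec), as.data.frame(rec2))
})

test_that("empty stop tables and CRS mismatches are handled", {
  cfg <- scenario_config(seed = 2, grid_shape = c(24, 24), n_fires = 1)
  sc <- null_scenario(cfg)
  empty <- sc$stops[0, ]
  rec <- attribute_all(empty, sc$scene, sc$cube, sc$stack)
  expect_equal(nrow(rec), 0)
  cube_bad <- sc$cube; cube_bad$crs <- "other"
  expect_error(attribute_all(sc$stops, sc$scene, cube_bad, sc$stack),
               "CRS mismatch.*weather_cube")
})
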