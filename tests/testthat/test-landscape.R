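# a minimal straight-edge world: columns 1..edge_col burned, rest unburned
straight_world <- function(nrc = 20, edge_col = 10, doy = 200) {
  m <- matrix(0L, nrc, nrc)
  m[, 1:edge_col] <- doy
  burn_scene(m, matrix(as.integer(m > 0), nrc, nrc))
}

uniform_stack <- function(scene, tree = 45, agb = 48, elev = 200,
                          lc = 1, years = 60, res = 100) {
  n <- nrow(scene$day_of_burn) * scene$pixel_size / res
  mk <- function(v, kind = "continuous") {
    landscape_layer(matrix(v, n, n), res, kind)
  }
  landscape_stack(list(
    tree_cover = mk(tree), agb = mk(agb), elevation = mk(elev),
    land_cover = mk(lc, "categorical"), burn_history = mk(years),
    road = mk(0, "binary"), water = mk(0, "binary")),
    origin = scene$origin)
}

mid_east_stop <- function(scene) {
  stops <- extract_fire_stops(scene)
  n <- nrow(scene$day_of_burn)
  stops[stops$row == n %/% 2 & stops$dir_x == 1, ][1, ]
}

test_that("the oriented ellipse has the prescribed geometry", {
  sc <- straight_world()
  s <- mid_east_stop(sc)
  e <- build_ellipse(s, sc)
  expect_equal(2 * e$a, 900)   # major axis = 3 x 300 m
  expect_equal(2 * e$b, 450)   # minor axis = 1.5 x 300 m
  # center is the midpoint of stop center and nearest burned center:
  # stop (450, 150) with burned neighbor (150, 150) -> (300, 150)
  m <- matrix(0L, 1, 2); m[1, 1] <- 100L
  tiny <- burn_scene(m, matrix(as.integer(m > 0), 1, 2))
  st <- extract_fire_stops(tiny)
  st1 <- st[st$row == 1 & st$col == 2, ]
  e2 <- build_ellipse(st1, tiny)
  expect_equal(c(e2$center_x, e2$center_y), c(300, 150))
  expect_equal(c(e2$dir_x, e2$dir_y), c(1, 0))
  # undefined direction -> no ellipse
  s_bad <- s; s_bad$direction_defined <- FALSE
  expect_null(build_ellipse(s_bad, sc))
})

test_that("ellipse sampling covers the ellipse and splits evenly on a straight edge", {
  sc <- straight_world()
  st <- uniform_stack(sc)
  s <- mid_east_stop(sc)
  e <- build_ellipse(s, sc)
  smp <- sample_ellipse(e, sc, st)
  # brute-force the expected lattice count
  K <- ceiling(e$a / 100)
  off <- (seq(-K, K - 1) + 0.5) * 100
  g <- expand.grid(ox = off, oy = off)
  inside <- (g$ox / e$a)^2 + (g$oy / e$b)^2 < 1  # axis-aligned orientation
  expect_equal(nrow(smp), sum(inside))
  # coverage: count * step^2 close to the ellipse area
  cover <- nrow(smp) * 100^2 / (pi * e$a * e$b)
  expect_gte(cover, 0.85); expect_lte(cover, 1.1)
  # straight perimeter: burned fraction near one half
  frac <- mean(smp$burned)
  expect_gte(frac, 0.4); expect_lte(frac, 0.6)
  # homogeneous layer: group means equal
  expect_equal(mean(smp$tree_cover[smp$burned]),
               mean(smp$tree_cover[!smp$burned]))
  expect_true(all((smp$u / e$a)^2 + (smp$w / e$b)^2 < 1))
})

test_that("continuous tests gate on significance and direction", {
  sc <- straight_world()
  st <- uniform_stack(sc)
  s <- mid_east_stop(sc)
  e <- build_ellipse(s, sc)
  smp <- sample_ellipse(e, sc, st)
  # plant the reported tree-cover contrast: 45% inside, 26% outside
  withr::with_seed(31, {
    smp$tree_cover <- ifelse(smp$burned, 45, 26) + rnorm(nrow(smp), 0, 5)
  })
  r <- test_continuous(smp, "tree_cover", "decrease")
  expect_true(r$pass)
  or <- oracle_welch_p(smp$tree_cover[!smp$burned], smp$tree_cover[smp$burned])
  expect_equal(r$p, or$p, tolerance = 1e-12)
  # identical groups: no pass
  smp2 <- smp; smp2$tree_cover <- 45
  expect_false(test_continuous(smp2, "tree_cover", "decrease")$pass)
  expect_equal(test_continuous(smp2, "tree_cover", "decrease")$p, 1)
  # higher outside fails the decline gate no matter the p-value
  smp3 <- smp; smp3$tree_cover <- ifelse(smp3$burned, 20, 60)
  expect_false(test_continuous(smp3, "tree_cover", "decrease")$pass)
})

test_that("categorical tests follow the contingency oracle with direction gates", {
  # water: 0/15 inside vs 12/17 outside
  smp <- tibble::tibble(
    burned = rep(c(TRUE, FALSE), c(15, 17)),
    water = c(rep(0, 15), rep(1, 12), rep(0, 5)))
  r <- test_categorical(smp, "water", mode = "presence")
  expect_true(r$pass); expect_true(r$direction_ok)
  tab <- rbind(inside = c(`0` = 15, `1` = 0), outside = c(`0` = 5, `1` = 12))
  or <- oracle_chisq_p(tab, correct = TRUE)
  expect_equal(r$p, or$p, tolerance = 1e-12)
  expect_equal(r$chisq, or$stat, tolerance = 1e-12)
  # identical distributions: chi-squared 0, p 1
  smp2 <- tibble::tibble(burned = rep(c(TRUE, FALSE), each = 10),
                         water = rep(c(0, 1), 10))
  r2 <- test_categorical(smp2, "water", mode = "presence")
  expect_equal(r2$p, 1, tolerance = 1e-12)
  expect_false(r2$pass)
  # water higher inside: direction gate blocks the pass
  smp3 <- tibble::tibble(burned = rep(c(TRUE, FALSE), c(15, 15)),
                         water = c(rep(1, 12), rep(0, 3), rep(0, 15)))
  r3 <- test_categorical(smp3, "water", mode = "presence")
  expect_false(r3$pass); expect_false(r3$direction_ok)
  expect_true(r3$p < 0.01)
  # sparse 2x2 with expected counts below 1 is skipped
  smp4 <- tibble::tibble(burned = rep(c(TRUE, FALSE), c(15, 15)),
                         water = c(rep(0, 15), rep(0, 14), 1))
  r4 <- test_categorical(smp4, "water", mode = "presence")
  expect_true(r4$skipped); expect_false(r4$pass)
  # land cover: largest relative gain outside must differ from the modal
  # class inside
  smp5 <- tibble::tibble(burned = rep(c(TRUE, FALSE), each = 14),
                         land_cover = c(rep(1, 14), rep(2, 12), rep(1, 2)))
  r5 <- test_categorical(smp5, "land_cover", mode = "landcover")
  expect_true(r5$pass); expect_true(r5$direction_ok)
})

test_that("the downslope rule needs both significance and a -5 degree slope", {
  sc <- straight_world()
  st <- uniform_stack(sc)
  s <- mid_east_stop(sc)
  e <- build_ellipse(s, sc)
  base <- sample_ellipse(e, sc, st)
  # flat terrain: no flag
  expect_false(test_downslope(base)$pass)
  ramp <- function(deg, noise_sd = 0.5) {
    withr::with_seed(41, {
      base$elevation <- 200 - tan(abs(deg) * pi / 180) * (base$u + 450) +
        rnorm(nrow(base), 0, noise_sd)
    })
    base
  }
  r10 <- test_downslope(ramp(10))
  expect_true(r10$pass)
  # slope recomputed by an independent linear fit on the group means
  d <- ramp(10)
  slope_or <- atan2(mean(d$elevation[!d$burned]) - mean(d$elevation[d$burned]),
                    mean(d$u[!d$burned]) - mean(d$u[d$burned])) * 180 / pi
  expect_equal(r10$slope_deg, slope_or, tolerance = 1e-9)
  expect_lt(r10$slope_deg, -5)
  # a significant but gentle -3 degree decline is not flagged
  r3 <- test_downslope(ramp(3, noise_sd = 0.2))
  expect_true(r3$p < 0.01)
  expect_false(r3$pass)
  expect_gt(r3$slope_deg, -5)
})

test_that("fuel load combines the tree-cover and AGB outcomes", {
  expect_true(combine_fuel_load(TRUE, FALSE))
  expect_true(combine_fuel_load(FALSE, TRUE))
  expect_true(combine_fuel_load(TRUE, TRUE))
  expect_false(combine_fuel_load(FALSE, FALSE))
  expect_false(combine_fuel_load(NA, FALSE))
})

test_that("landscape attribution is equivariant under 90-degree rotation", {
  # layer noise kept small so no test sits near the significance threshold:
  # nearest-cell ties at exact cell boundaries resolve differently after
  # rotation, shifting single samples between cells, which only matters for
  # borderline p-values
  cfg <- scenario_config(seed = 23, grid_shape = c(36, 36),
                         fires = fire_spec(c(18, 16), n_days = 7),
                         noise = list(tree_cover = 1, agb = 1),
                         planted_causes = cause_spec("fuel_load_edge",
                                                     distance_px = 4))
  sc <- generate_scenario(cfg)
  res <- attribute_landscape_all(sc$stops, sc$scene, sc$stack)

  # rotate world 90 deg counterclockwise: (row, col) -> (nr - col + 1, row)
  rot <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  scene_r <- burn_scene(rot(sc$scene$day_of_burn), rot(sc$scene$fire_id),
                        sc$scene$pixel_size)
  layers_r <- lapply(sc$stack$layers, function(l) {
    landscape_layer(rot(l$values), l$res, l$kind)
  })
  stack_r <- landscape_stack(layers_r, origin = c(0, ncol(sc$scene$day_of_burn) *
                                                    sc$scene$pixel_size))
  stops_r <- extract_fire_stops(scene_r)
  res_r <- attribute_landscape_all(stops_r, scene_r, stack_r)

  # match stops through the rotation and compare flags; stops with a sample
  # point exactly on a raster cell boundary are excluded, because the
  # deterministic lower-index tie-break is not itself rotation-equivariant
  # (real, unaligned data never produces exact ties)
  n <- nrow(sc$scene$day_of_burn)
  key <- paste(n - sc$stops$col + 1, sc$stops$row)
  key_r <- paste(stops_r$row, stops_r$col)
  m <- match(key, key_r)
  expect_false(any(is.na(m)))
  burned_at <- function(scn, x, y) {
    nr2 <- nrow(scn$day_of_burn); nc2 <- ncol(scn$day_of_burn)
    rr <- pmin(pmax(ceiling((nr2 * 300 - y) / 300), 1), nr2)
    cc <- pmin(pmax(ceiling(x / 300), 1), nc2)
    scn$day_of_burn[cbind(rr, cc)] > 0
  }
  clean <- vapply(seq_len(nrow(sc$stops)), function(i) {
    e <- build_ellipse(sc$stops[i, ], sc$scene)
    s <- sample_ellipse(e, sc$scene, sc$stack)
    # a boundary tie is harmless unless the adjacent cells disagree on the
    # burned flag: nudge every sample half a meter both ways and compare
    all(burned_at(sc$scene, s$x - 0.5, s$y) == burned_at(sc$scene, s$x + 0.5, s$y)) &&
      all(burned_at(sc$scene, s$x, s$y - 0.5) == burned_at(sc$scene, s$x, s$y + 0.5))
  }, logical(1))
  expect_gt(sum(clean), nrow(sc$stops) / 2)
  for (cl in c("fuel_load_flag", "water_flag", "downslope_flag",
               "land_cover_flag", "burn_history_flag")) {
    expect_equal(res[[cl]][clean], res_r[[cl]][m][clean])
  }
})
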