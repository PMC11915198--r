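test_that("VPD follows the Magnus saturation form", {
  # saturated air has zero deficit
  expect_equal(compute_vpd(15, 15), 0)
  # standard saturation-pressure table values: e_s(20 C) = 2.339 kPa,
  # e_s(10 C) = 1.228 kPa, e_s(30 C) = 4.243 kPa, e_s(15 C) = 1.705 kPa
  expect_equal(compute_vpd(20, 10), 2.339 - 1.228, tolerance = 0.01)
  expect_equal(compute_vpd(30, 15), 4.243 - 1.705, tolerance = 0.01)
  # dewpoint above temperature is clamped, not negative
  expect_equal(compute_vpd(15, 15.3), 0)
  expect_true(is.na(compute_vpd(NA, 10)))
  expect_true(all(compute_vpd(c(25, 18), c(12, 17)) > 0))
})

test_that("WFSI is the wind projection on the outward direction", {
  expect_equal(compute_wfsi(5, 0, 1, 0), 5)     # wind along spread
  expect_equal(compute_wfsi(-5, 0, 1, 0), -5)   # opposing
  expect_equal(compute_wfsi(0, 5, 1, 0), 0)     # perpendicular
  # invariant under joint rotation of wind and direction
  withr::with_seed(3, {
    for (i in 1:20) {
      u <- rnorm(1, 0, 5); v <- rnorm(1, 0, 5)
      th0 <- runif(1, 0, 2 * pi); th <- runif(1, 0, 2 * pi)
      d <- c(cos(th0), sin(th0))
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      wv <- rot %*% c(u, v); dv <- rot %*% d
      expect_equal(compute_wfsi(u, v, d[1], d[2]),
                   compute_wfsi(wv[1], wv[2], dv[1], dv[2]),
                   tolerance = 1e-12)
    }
  })
})

test_that("split t-test gates on significance and direction", {
  expect_equal(split_ttest(rep(1, 240))$p, 1)
  expect_false(split_ttest(rep(1, 240))$pass)

  withr::with_seed(8, {
    x <- c(rnorm(120, 1.5, 0.2), rnorm(120, 0.5, 0.2))
    r <- split_ttest(x, direction = "decline")
    expect_true(r$pass)
    # p matches the Welch oracle to near machine precision
    or <- oracle_welch_p(x[121:240], x[1:120])
    expect_equal(r$p, or$p, tolerance = 1e-12)
    expect_equal(r$t, or$t, tolerance = 1e-12)
    # an increase tested as decline never passes
    expect_false(split_ttest(x, direction = "increase")$pass)
    expect_true(split_ttest(x, direction = "increase")$p < 0.01)
  })
  # zero variance, unequal means: reported at the machine floor
  z <- c(rep(1, 120), rep(0, 120))
  r <- split_ttest(z, direction = "decline")
  expect_true(r$pass)
  expect_lte(r$p, .Machine$double.xmin)
})

test_that("windows are extracted from the containing weather cell", {
  cfg <- scenario_config(seed = 2, noise = list(vpd = 0, sm = 0, wind = 0),
                         baseline = list(vpd_amp = 0, t2m_amp = 0),
                         planted_causes = cause_spec("vpd_drop", size = 1))
  sc <- generate_scenario(cfg)
  s <- sc$stops[sc$stops$last_burn_date == sc$halt_doy[1], ][1, ]
  w <- extract_window(sc$cube, s)
  expect_s3_class(w, "fs_window")
  expect_equal(nrow(w), 240)
  expect_true(attr(w, "complete"))
  # planted step at the burn-day boundary shows at index 120/121
  expect_equal(w$vpd[121] - w$vpd[120], -1, tolerance = 1e-9)
  expect_equal(unique(w$vpd[1:120]), cfg$baseline$vpd_mean, tolerance = 1e-9)

  # a stop too close to the cube's time edge is marked incomplete
  s2 <- s; s2$last_burn_date <- sc$cube$start_doy + 2L
  w2 <- extract_window(sc$cube, s2)
  expect_false(attr(w2, "complete"))
  expect_true(all(is.na(w2$vpd)))
})

test_that("two-stage weather attribution flags planted changes only in the timing window", {
  mk_window <- function(vpd, sm = rep(0.25, 240), wfsi = rep(0, 240)) {
    structure(tibble::tibble(hour = 1:240, doy = rep(1:10, each = 24),
                             vpd = vpd, sm = sm, wfsi = wfsi),
              split_index = 120L, burn_doy = 5L, complete = TRUE,
              class = c("fs_window", "tbl_df", "tbl", "data.frame"))
  }
  withr::with_seed(21, {
    # VPD step at the burn-day boundary -> vpd + fuel moisture flags
    vpd <- c(rnorm(120, 1.5, 0.1), rnorm(120, 0.5, 0.1))
    a <- attribute_weather(mk_window(vpd))
    expect_true(a$vpd_flag); expect_true(a$fuel_moisture)
    expect_false(a$sm_flag); expect_false(a$wfsi_flag)

    # same magnitude, but the break 4 days after the burn date: t-test may
    # pass, the timing window must not
    vpd_late <- c(rnorm(216, 1.5, 0.1), rnorm(24, -0.5, 0.1))
    a2 <- attribute_weather(mk_window(vpd_late))
    expect_false(a2$vpd_flag)
    expect_false(a2$fuel_moisture)

    # flat VPD + soil moisture rise -> fuel moisture via sm only
    sm <- c(rnorm(120, 0.20, 0.01), rnorm(120, 0.30, 0.01))
    a3 <- attribute_weather(mk_window(rnorm(240, 1.2, 0.1), sm = sm))
    expect_true(a3$sm_flag); expect_true(a3$fuel_moisture)
    expect_false(a3$vpd_flag)
  })
})

test_that("a 3-SD planted step at the burn day is flagged in at least 95% of stops", {
  # eight fires, each with a VPD step of three within-noise SDs planted at
  # its halt day; over 500 labeled stops
  pos <- expand.grid(r = c(14, 38, 62, 86), c = c(14, 38, 62, 86))[1:8, ]
  fires <- lapply(1:8, function(i) fire_spec(c(pos$r[i], pos$c[i]), n_days = 9))
  causes <- lapply(1:8, function(i) cause_spec("vpd_drop", size = 3 * 0.15,
                                               fire = i))
  cfg <- scenario_config(seed = 700, grid_shape = c(100, 100), fires = fires,
                         planted_causes = causes)
  syn <- generate_scenario(cfg)
  has <- lengths(syn$truth$causes) > 0
  stops <- syn$stops[syn$stops$stop_id %in% syn$truth$stop_id[has], ]
  expect_gte(nrow(stops), 500)
  wx <- attribute_weather_all(stops, syn$cube)
  expect_gte(mean(wx$fuel_moisture), 0.95)
})
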