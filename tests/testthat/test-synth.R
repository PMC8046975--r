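test_that("identical configuration and seed reproduce the record stream exactly", {
  cfg <- synth_config(list(site_config("S")), end = "2016-06-15", seed = 11)
  a <- generate_campaign(cfg, truth = FALSE)
  b <- generate_campaign(cfg, truth = FALSE)
  expect_identical(a$records, b$records)
  expect_identical(a$injections, b$injections)
})

test_that("identity coupling with zero noise makes the two positions identical", {
  s <- quiet_site("S",
    coupling_intercept = 0, coupling_slope = 1,
    hourly_slope_profile = rep(1, 24)
  )
  camp <- generate_campaign(year_config(s, end = "2016-07-31"),
                            variables = "air_T", truth = FALSE)
  wide <- tidyr::pivot_wider(camp$records, id_cols = "timestamp",
                             names_from = "position", values_from = "value")
  expect_equal(wide$below_canopy, wide$open_field)
})

test_that("zero-noise coupling line is recovered by daily-mean OLS to machine precision", {
  s <- quiet_site("S", hourly_slope_profile = rep(1, 24))
  # coupling line (3.65, 0.60): daily means inherit it exactly
  r <- suppressWarnings(recover_coupling_slope(s, seed = 1))
  expect_equal(r$alpha, 3.65, tolerance = 1e-10)
  expect_equal(r$beta, 0.60, tolerance = 1e-10)
})

test_that("gap injection hits the configured missing fraction", {
  s <- quiet_site("S", gap_fraction = 0.05)
  camp <- generate_campaign(year_config(s), variables = "air_T", truth = FALSE)
  one <- dplyr::filter(camp$records, position == "open_field")
  n <- nrow(one)
  frac <- mean(is.na(one$value))
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac - 0.05), 4 * se)
})

test_that("zero-noise empirical growing-season offset equals the ground truth exactly", {
  s <- quiet_site("S")
  cfg <- year_config(s)
  camp <- generate_campaign(cfg, variables = "air_T", truth = FALSE)
  clean <- screen_outliers(camp$records)
  pos <- split_positions(clean)
  deltas <- select_season(compute_offset_series(pos$below, pos$open), "GS")
  expect_equal(mean(deltas$delta), true_mean_offset(s, cfg, "GS"),
               tolerance = 1e-12)
})

test_that("soil temperature sits within the zero-curtain band inside snow windows", {
  s <- site_config("NW", outlier_fraction = 0)
  camp <- generate_campaign(year_config(s, end = "2017-06-30"),
                            variables = c("air_T", "soil_T"), truth = FALSE)
  soil <- dplyr::filter(camp$records, variable == "soil_T",
                        position == "below_canopy")
  in_win <- as.Date(soil$timestamp) >= as.Date("2016-11-15") &
    as.Date(soil$timestamp) <= as.Date("2017-04-10")
  v <- soil$value[in_win & !is.na(soil$value)]
  expect_true(all(v >= -0.3 & v <= 0.3))
})

test_that("soil moisture is non-increasing between wet-up events", {
  s <- quiet_site("S")
  camp <- generate_campaign(year_config(s, end = "2016-08-31"),
                            variables = c("air_T", "soil_m"), truth = FALSE)
  m <- dplyr::filter(camp$records, variable == "soil_m",
                     position == "open_field")$value
  jumps <- diff(m)
  # upward steps only at wet-up events, whose frequency matches the
  # configured rain rate; every other step dries down
  p_event <- 0.35 * 30 / 1440
  n <- length(jumps)
  expect_lt(abs(mean(jumps > 0) - p_event), 4 * sqrt(p_event / n))
  expect_true(all(jumps[jumps <= 0] <= 1e-12))
  expect_gt(sum(jumps < 0), n * 0.9)
})

test_that("overlapping snow windows and degenerate date ranges are rejected", {
  expect_error(
    site_config("NW", snow_windows = list(
      below_canopy = list(c("2016-11-01", "2016-12-15"),
                          c("2016-12-01", "2017-01-15")),
      open_field = list()
    )),
    "overlapping"
  )
  expect_error(synth_config(start = "2017-01-01", end = "2016-01-01"),
               "degenerate")
  expect_error(synth_config(step_minutes = 45), "step_minutes")
})

test_that("NDVI curve crosses half-amplitude at SOS and EOS with the right extrema", {
  nd <- generate_ndvi_series(sos = 120, eos = 340, base = 0.3,
                             amplitude = 0.4, noise_sd = 0)
  # dense evaluation of the same family for crossing/extrema checks
  thr <- 0.3 + 0.2
  above <- nd$ndvi >= thr
  up <- which(diff(above) == 1)[1]
  down <- rev(which(diff(above) == -1))[1]
  cross_up <- approx(nd$ndvi[up:(up + 1)], nd$doy[up:(up + 1)], xout = thr)$y
  cross_down <- approx(nd$ndvi[down:(down + 1)], nd$doy[down:(down + 1)],
                       xout = thr)$y
  expect_lt(abs(cross_up - 120), 8)    # within half the composite step
  expect_lt(abs(cross_down - 340), 8)
  expect_equal(max(nd$ndvi), 0.7, tolerance = 0.01)
  expect_equal(min(nd$ndvi), 0.3, tolerance = 0.01)
  expect_error(generate_ndvi_series(120, 340, amplitude = 0), "amplitude")
  expect_error(generate_ndvi_series(340, 120), "sos")
})

test_that("calibration helpers hit their targets exactly", {
  cfg <- year_config(site_config("S"))
  s <- calibrate_mean_offset(site_config("S"), cfg, -2.41, "GS")
  expect_equal(true_mean_offset(s, cfg, "GS"), -2.41, tolerance = 1e-10)
  s2 <- calibrate_coupling_slope(site_config("S"), cfg, 0.60)
  expect_equal(true_daily_slope(s2, cfg, "GS"), 0.60, tolerance = 1e-10)
})
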