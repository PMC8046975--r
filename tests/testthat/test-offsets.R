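mk_pos <- function(values, position, flag = NULL, start = "2016-06-01") {
  ts <- seq(as.POSIXct(paste(start, "00:00"), tz = "UTC"),
            by = 1800, length.out = length(values))
  out <- tibble::tibble(timestamp = ts, site = "S", position = position,
                        variable = "air_T", value = values)
  if (!is.null(flag)) out$qc_flag <- flag
  out
}

test_that("offset series is zero for identical inputs and constant for shifts", {
  v <- sin(seq(0, 10, length.out = 96)) + 10
  expect_true(all(compute_offset_series(mk_pos(v, "below_canopy"),
                                        mk_pos(v, "open_field"))$delta == 0))
  d <- compute_offset_series(mk_pos(v - 2.4, "below_canopy"),
                             mk_pos(v, "open_field"))
  expect_equal(unique(d$delta), -2.4)
})

test_that("flagged records drop the matched offset and disjoint grids error", {
  v <- rnorm(96) + 10
  flags <- rep("ok", 96); flags[10] <- "outlier"
  d <- compute_offset_series(mk_pos(v, "below_canopy", flags),
                             mk_pos(v, "open_field"))
  expect_equal(nrow(d), 95)
  expect_false(mk_pos(v, "below_canopy")$timestamp[10] %in% d$timestamp)
  shifted <- mk_pos(v, "open_field", start = "2017-01-01")
  expect_error(compute_offset_series(mk_pos(v, "below_canopy"), shifted),
               "disjoint")
})

test_that("swapping the positions negates every offset and the seasonal mean", {
  s <- site_config("S", gap_fraction = 0.01)
  camp <- generate_campaign(year_config(s, seed = 6, end = "2016-09-30"),
                            variables = "air_T", truth = FALSE)
  clean <- screen_outliers(camp$records)
  pos <- split_positions(clean)
  d1 <- compute_offset_series(pos$below, pos$open)
  d2 <- compute_offset_series(pos$open, pos$below)
  expect_equal(d1$delta, -d2$delta)
  t1 <- seasonal_offset_table(pos$below, pos$open, seasons = "JJA",
                              statistics = "mean")
  t2 <- seasonal_offset_table(pos$open, pos$below, seasons = "JJA",
                              statistics = "mean")
  expect_equal(t1$mu, -t2$mu, tolerance = 1e-6)
})

test_that("the mean seasonal estimator equals the arithmetic mean on noise-free data", {
  s <- quiet_site("S")
  camp <- generate_campaign(year_config(s, end = "2016-09-30"),
                            variables = "air_T", truth = FALSE)
  clean <- screen_outliers(camp$records)
  pos <- split_positions(clean)
  deltas <- select_season(compute_offset_series(pos$below, pos$open), "JJA")
  tab <- seasonal_offset_table(pos$below, pos$open, seasons = "JJA",
                               statistics = "mean")
  # REML weights months by information; with 30/31/31-day months the GLS
  # intercept differs from the arithmetic mean by the month-length imbalance
  expect_equal(tab$mu, mean(deltas$delta), tolerance = 5e-3)
})

test_that("a campaign with zero configured winter offset covers zero in DJF", {
  cfg <- year_config(site_config("S"))
  s0 <- calibrate_mean_offset(site_config("S"), cfg, 0, "DJF")
  covered <- 0
  for (sd in 1:3) {
    r <- recover_seasonal_offset(s0, seed = sd, season = "DJF")
    covered <- covered + (abs(r$mu) <= 2 * r$se)
  }
  expect_gte(covered, 2)
})

test_that("daily-extreme offsets are differences of per-day extremes", {
  # construct one day where max(b) - max(o) differs from max(b - o)
  o <- c(rep(0, 24), rep(10, 24))
  b <- c(rep(5, 24), rep(8, 24))
  tab <- seasonal_offset_table(
    mk_pos(rep(b, 20), "below_canopy"), mk_pos(rep(o, 20), "open_field"),
    seasons = "JJA", statistics = "daily_max", min_days = 5
  )
  expect_equal(tab$mu, -2, tolerance = 1e-8)  # 8 - 10, not max(b - o) = 5
})

test_that("hourly coupling is flat for identity data and dips where the profile dips", {
  v <- rnorm(48 * 40, 12, 4)
  hp <- hourly_coupling_profile(mk_pos(v, "below_canopy"),
                                mk_pos(v, "open_field"))
  expect_equal(hp$slope, rep(1, 24), tolerance = 1e-9)
  expect_true(all(hp$coupled))

  # S-style profile with midday dip, quiet random effects so the hourly
  # slopes sit at beta * p_h
  s <- quiet_site("S", ar1_sd = 1.2, synoptic_sd = 2.2)
  camp <- generate_campaign(year_config(s, seed = 2, end = "2016-09-30"),
                            variables = "air_T", truth = FALSE)
  clean <- screen_outliers(camp$records)
  pos <- split_positions(clean)
  hp2 <- hourly_coupling_profile(pos$below, pos$open)
  midday <- hp2$coupled[hp2$hour %in% 10:13]
  night <- hp2$coupled[hp2$hour %in% c(23, 0:7)]
  expect_true(all(!midday))
  expect_true(all(night))
})

test_that("hourly slopes are invariant to shuffling within the hour", {
  set.seed(8)
  v <- rnorm(48 * 35, 12, 4)
  below <- mk_pos(0.5 * v + 1, "below_canopy")
  open <- mk_pos(v, "open_field")
  hp1 <- hourly_coupling_profile(below, open)
  # shuffle paired rows within one hour (permuting days leaves OLS unchanged)
  idx <- which(lubridate::hour(open$timestamp) == 9)
  perm <- sample(idx)
  below2 <- below; open2 <- open
  below2$value[idx] <- below$value[perm]
  open2$value[idx] <- open$value[perm]
  hp2 <- hourly_coupling_profile(below2, open2)
  expect_equal(hp1$slope, hp2$slope, tolerance = 1e-12)
})
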