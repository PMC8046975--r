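#' Model-implied true seasonal mean temperature offset
#'
#' The generator's below-canopy temperature is
#' \eqn{T_{in} = \alpha + \beta p_h T_{out} + \mathrm{RE} + \epsilon}, so the
#' offset \eqn{\Delta T = T_{in} - T_{out}} has expectation
#' \eqn{\alpha + (\beta p_h - 1)\,T^{det}_{out}(t)} at every grid time; the
#' seasonal truth is the average of that quantity over the season's grid.
#' Noise and random intercepts have mean zero, so this is exact.
#'
#' @param site A [site_config()].
#' @param config A [synth_config()] providing the time grid (the site need
#'   not be listed in it).
#' @param season `"GS"`, `"JJA"` or `"DJF"`.
#' @return Mean offset in degC (negative = cooler below canopy).
#' @export
true_mean_offset <- function(site, config, season = "GS") {
  ts <- campaign_grid(config)
  ts <- ts[lubridate::month(ts) %in% season_months(season)]
  t_open <- deterministic_open_T(site, ts)
  p <- site$hourly_slope_profile[lubridate::hour(ts) + 1L]
  site$coupling_intercept + mean((site$coupling_slope * p - 1) * t_open)
}

#' Model-implied true slope of the daily-mean coupling regression
#'
#' Expected slope of the OLS regression of daily-mean below-canopy on
#' daily-mean open-field temperature over a season. The deterministic
#' day-to-day covariance is combined with the AR(1) noise contribution to the
#' daily means: shared open-field noise enters the below-canopy series scaled
#' by \eqn{\beta p_h}, so the noise adds \eqn{\beta c_{pe}} to the covariance
#' and \eqn{v_e} to the predictor variance, where \eqn{c_{pe}} and
#' \eqn{v_e} follow from the within-day AR(1) autocovariance.
#'
#' @inheritParams true_mean_offset
#' @return Unitless slope.
#' @export
true_daily_slope <- function(site, config, season = "GS") {
  ts <- campaign_grid(config)
  keep <- lubridate::month(ts) %in% season_months(season)
  ts <- ts[keep]
  t_open <- deterministic_open_T(site, ts)
  p <- site$hourly_slope_profile[lubridate::hour(ts) + 1L]
  day <- as.Date(ts)
  s_d <- tapply(t_open, day, mean)                 # open-field daily means
  m_d <- tapply(p * t_open, day, mean)             # profile-weighted means
  beta <- site$coupling_slope
  cov_det <- beta * stats::cov(m_d, s_d)
  var_det <- var(s_d)
  # AR(1) noise contribution to daily means (slots per day from the grid).
  n_slot <- round(1440 / config$step_minutes)
  rho <- site$ar1_rho
  gam <- site$ar1_sd^2 * rho^abs(outer(seq_len(n_slot), seq_len(n_slot), "-"))
  p_slot <- site$hourly_slope_profile[
    floor((seq_len(n_slot) - 1) * config$step_minutes / 60) %% 24 + 1L]
  v_e <- sum(gam) / n_slot^2
  c_pe <- sum(p_slot * rowSums(gam)) / n_slot^2
  # day-scale synoptic state: enters the open-field daily mean fully and the
  # below-canopy daily mean through beta * mean(p_h)
  v_s <- site$synoptic_sd^2
  c_ps <- mean(p_slot) * v_s
  unname((cov_det + beta * (c_pe + c_ps)) / (var_det + v_e + v_s))
}

#' Model-implied expected seasonal daily-maximum temperature offset
#'
#' Expectation of the seasonal mean of (daily max below-canopy minus daily
#' max open-field). Unlike the mean offset this has no closed form: the
#' maximum of a noisy series is biased upward relative to the noise-free
#' maximum, by different amounts for the two positions. The expectation is
#' evaluated by Monte-Carlo quadrature over the noise, random-effect, and
#' gap distributions, with a fixed internal quadrature seed so the value is a
#' deterministic function of the configuration (independent of the campaign
#' seed). Days are treated as independent AR(1) segments, a negligible
#' approximation to the continuous campaign noise.
#'
#' @inheritParams true_mean_offset
#' @param season Season over which daily maxima are averaged.
#' @param n_rep Monte-Carlo replicates per day.
#' @param profile_scale Optional multiplier applied to the hourly slope
#'   profile (used by [calibrate_daily_max_offset()]).
#' @param noise Optional pre-generated noise list (common random numbers for
#'   calibration); see the source for its layout.
#' @return Expected mean daily-max offset in degC.
#' @export
expected_daily_max_offset <- function(site, config, season = "JJA",
                                      n_rep = 150, profile_scale = 1,
                                      noise = NULL) {
  ts <- campaign_grid(config)
  ts <- ts[lubridate::month(ts) %in% season_months(season)]
  day <- as.Date(ts)
  days <- unique(day)
  n_slot <- round(1440 / config$step_minutes)
  if (length(ts) != length(days) * n_slot) {
    stop("season grid is not whole days", call. = FALSE)
  }
  t_det <- matrix(deterministic_open_T(site, ts), nrow = n_slot)
  hr <- matrix(lubridate::hour(ts), nrow = n_slot)[, 1]
  p <- profile_scale * site$hourly_slope_profile[hr + 1L]
  m <- ncol(t_det) * n_rep
  if (is.null(noise)) {
    noise <- with_seed(104729L, daily_max_noise(site, config, ncol(t_det), n_rep, n_slot, hr))
  }
  det_rep <- t_det[, rep(seq_len(ncol(t_det)), each = n_rep)]
  t_out <- det_rep + noise$e_open
  t_in <- site$coupling_intercept + site$coupling_slope * p * t_out +
    noise$e_can + noise$re_day + noise$re_hour
  t_out[noise$gap_open] <- NA
  t_in[noise$gap_can] <- NA
  max_out <- suppressWarnings(apply(t_out, 2, max, na.rm = TRUE))
  max_in <- suppressWarnings(apply(t_in, 2, max, na.rm = TRUE))
  ok <- is.finite(max_out) & is.finite(max_in)
  mean(max_in[ok] - max_out[ok])
}

# Pre-generate all stochastic inputs for expected_daily_max_offset so that
# calibration can reuse them (common random numbers).
daily_max_noise <- function(site, config, n_day, n_rep, n_slot, hr) {
  m <- n_day * n_rep
  e_open <- ar1_matrix(n_slot, m, site$ar1_rho, site$ar1_sd) +
    matrix(rnorm(m, 0, site$synoptic_sd), n_slot, m, byrow = TRUE)
  e_can <- ar1_matrix(n_slot, m, site$ar1_rho,
                      site$canopy_noise_ratio * site$ar1_sd)
  re_day <- matrix(rnorm(m, 0, site$offset_random_sd_day),
                   n_slot, m, byrow = TRUE)
  hour_fac <- hr + 1L
  re_hour_draws <- matrix(rnorm(24 * m, 0, site$offset_random_sd_hour), 24, m)
  re_hour <- re_hour_draws[hour_fac, ]
  gap_open <- matrix(runif(n_slot * m) < site$gap_fraction, n_slot, m)
  gap_can <- matrix(runif(n_slot * m) < site$gap_fraction, n_slot, m)
  list(e_open = e_open, e_can = e_can, re_day = re_day, re_hour = re_hour,
       gap_open = gap_open, gap_can = gap_can)
}

#' Calibrate the coupling intercept to a target seasonal mean offset
#'
#' Shifts `coupling_intercept` so that [true_mean_offset()] for the given
#' season equals `target` exactly (the truth is linear in the intercept).
#'
#' @inheritParams true_mean_offset
#' @param target Target mean offset in degC (negative = cooler below canopy).
#' @return The modified `site_config`.
#' @export
calibrate_mean_offset <- function(site, config, target, season = "GS") {
  cur <- true_mean_offset(site, config, season)
  site$coupling_intercept <- site$coupling_intercept + (target - cur)
  site
}

#' Calibrate the coupling slope to a target daily-mean regression slope
#'
#' Rescales `coupling_slope` so that [true_daily_slope()] equals `target`;
#' the implied slope is proportional to \eqn{\beta}, so the solution is
#' exact.
#'
#' @inheritParams true_mean_offset
#' @param target Target daily-mean OLS slope.
#' @return The modified `site_config`.
#' @export
calibrate_coupling_slope <- function(site, config, target, season = "GS") {
  cur <- true_daily_slope(site, config, season)
  site$coupling_slope <- site$coupling_slope * target / cur
  validate_site_config(site)
}

#' Calibrate the hourly profile to a target daily-maximum offset
#'
#' Rescales the hour-of-day slope profile by a common factor, chosen by root
#' finding so that [expected_daily_max_offset()] equals `target`. Common
#' random numbers make the Monte-Carlo objective smooth in the scale factor.
#'
#' @inheritParams expected_daily_max_offset
#' @param target Target mean daily-max offset in degC (typically negative).
#' @param interval Search interval for the profile scale factor.
#' @return The modified `site_config`.
#' @export
calibrate_daily_max_offset <- function(site, config, target, season = "JJA",
                                       n_rep = 150, interval = c(0.3, 1.6)) {
  ts <- campaign_grid(config)
  ts <- ts[lubridate::month(ts) %in% season_months(season)]
  n_slot <- round(1440 / config$step_minutes)
  hr <- matrix(lubridate::hour(ts), nrow = n_slot)[, 1]
  n_day <- length(ts) / n_slot
  noise <- with_seed(104729L,
    daily_max_noise(site, config, n_day, n_rep, n_slot, hr))
  f <- function(s) {
    expected_daily_max_offset(site, config, season, n_rep,
                              profile_scale = s, noise = noise) - target
  }
  root <- uniroot(f, interval = interval, tol = 1e-4)
  site$hourly_slope_profile <- root$root * site$hourly_slope_profile
  validate_site_config(site)
}

# Assemble the ground-truth block for one site (all values implied by the
# configuration; nothing is read back from a simulated campaign).
site_ground_truth <- function(site, config, daily_max_reps = 120) {
  list(
    site_id = site$site_id,
    alpha_true = site$coupling_intercept,
    beta_true = site$coupling_slope,
    mean_offset = list(
      GS = true_mean_offset(site, config, "GS"),
      JJA = true_mean_offset(site, config, "JJA"),
      DJF = true_mean_offset(site, config, "DJF")
    ),
    daily_max_offset_JJA =
      expected_daily_max_offset(site, config, "JJA", n_rep = daily_max_reps),
    daily_slope_GS = true_daily_slope(site, config, "GS"),
    sos = site$ndvi_sos,
    eos = site$ndvi_eos,
    los = site$ndvi_eos - site$ndvi_sos,
    snow_windows = site$snow_windows
  )
}
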