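#' Site configuration for the synthetic campaign generator
#'
#' Builds the parameter set describing one monitoring site: the open-field
#' temperature climatology (annual and diurnal harmonics plus AR(1) noise),
#' the below-canopy coupling line (intercept \eqn{\alpha}, slope \eqn{\beta},
#' and an hour-of-day multiplier profile of the slope), nested month/day/hour
#' random-intercept standard deviations, snow windows that clamp soil
#' temperature near 0 degC, soil-moisture event dynamics with canopy
#' interception, and gap/outlier injection rates.
#'
#' Defaults emulate a pair of treeline stations on contrasting aspects:
#' `"S"` is a warm south-facing slope with a strongly decoupled midday
#' (coupling line 3.65 + 0.60 x) and alternating 5-day snow/no-snow blocks in
#' March; `"NW"` is a cooler northwest-facing slope with a denser canopy
#' (coupling line 1.73 + 0.76 x) and a long continuous snowpack (Nov 15 to
#' Apr 10 below canopy, Nov 15 to Mar 25 in the open).
#'
#' @param site_id `"NW"` or `"S"`; selects the default parameter set.
#' @param ... Named overrides for any field of the default configuration.
#'
#' @return A list of class `site_config`.
#' @export
#' @examples
#' cfg <- site_config("S", gap_fraction = 0)
#' cfg$coupling_slope
site_config <- function(site_id = c("NW", "S"), ...) {
  site_id <- match.arg(site_id)
  base <- list(
    site_id = site_id,
    annual_mean_T = 5.0,            # degC
    seasonal_amplitude = 8.8,       # degC, half-range of the annual harmonic
    seasonal_phase = 200,           # day-of-year of the annual maximum
    diurnal_amplitude_summer = 4.5, # degC
    diurnal_amplitude_winter = 2.0, # degC
    ar1_rho = 0.9,                  # per half-hour step
    ar1_sd = 1.2,                   # degC, stationary sd of open-field noise
    synoptic_sd = 2.2,              # degC, day-scale weather variability
    synoptic_rho = 0.7,             # day-to-day correlation of synoptic state
    canopy_noise_ratio = 0.5,       # below-canopy independent noise sd ratio
    coupling_intercept = 1.73,      # alpha, degC
    coupling_slope = 0.76,          # beta, unitless
    hourly_slope_profile = hourly_profile(1.20, 0.50),
    offset_random_sd_month = 0.30,  # degC
    offset_random_sd_day = 0.40,    # degC
    offset_random_sd_hour = 0.25,   # degC
    snow_windows = list(
      below_canopy = list(c("2016-11-15", "2017-04-10")),
      open_field   = list(c("2016-11-15", "2017-03-25"))
    ),
    soil_damping = 0.02,            # per-step smoothing weight in (0, 1]
    soil_lag = 2,                   # hours
    rain_rate = 0.35,               # events / day
    interception_fraction = 0.45,   # below-canopy wet-up reduction
    moisture_decay = 0.06,          # / day
    gap_fraction = 0.02,
    outlier_fraction = 0.002,
    ndvi_sos = 130, ndvi_eos = 310, # phenology truth (day-of-year)
    ndvi_base = 0.25, ndvi_amplitude = 0.45
  )
  if (site_id == "S") {
    base$annual_mean_T <- 8.5
    base$seasonal_amplitude <- 9.2
    base$diurnal_amplitude_summer <- 6.0
    base$diurnal_amplitude_winter <- 2.5
    base$coupling_intercept <- 3.65
    base$coupling_slope <- 0.60
    base$hourly_slope_profile <- hourly_profile(1.40, 0.95)
    base$interception_fraction <- 0.30
    base$snow_windows <- list(
      below_canopy = march_snow_blocks(),
      open_field   = march_snow_blocks()
    )
    base$ndvi_sos <- 120
    base$ndvi_eos <- 340
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown) > 0) {
    stop("unknown site_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base[names(over)] <- over
  validate_site_config(structure(base, class = "site_config"))
}

# Hour-of-day multipliers of the coupling slope: flat at night, with a
# daytime depression over 08:00-22:00 shaped as sin^2.
hourly_profile <- function(night_level, dip_depth) {
  h <- 0:23
  dip <- ifelse(h >= 8 & h <= 22, sin(pi * (h - 8) / 14)^2, 0)
  night_level - dip_depth * dip
}

# Alternating 5-day snow-on blocks through March (on 1-5, 11-15, 21-25).
march_snow_blocks <- function(year = 2017) {
  lapply(c(1, 11, 21), function(d) {
    c(sprintf("%d-03-%02d", year, d), sprintf("%d-03-%02d", year, d + 4))
  })
}

validate_site_config <- function(cfg) {
  stopifnot(
    cfg$coupling_slope > 0, cfg$coupling_slope <= 1,
    cfg$ar1_rho >= 0, cfg$ar1_rho < 1,
    cfg$ar1_sd >= 0,
    cfg$synoptic_sd >= 0,
    cfg$synoptic_rho >= 0, cfg$synoptic_rho < 1,
    length(cfg$hourly_slope_profile) == 24,
    all(cfg$hourly_slope_profile > 0),
    cfg$offset_random_sd_month >= 0,
    cfg$offset_random_sd_day >= 0,
    cfg$offset_random_sd_hour >= 0,
    cfg$soil_damping > 0, cfg$soil_damping <= 1,
    cfg$interception_fraction >= 0, cfg$interception_fraction < 1,
    cfg$gap_fraction >= 0, cfg$gap_fraction < 1,
    cfg$outlier_fraction >= 0, cfg$outlier_fraction < 1
  )
  for (pos in names(cfg$snow_windows)) {
    win <- snow_window_dates(cfg$snow_windows[[pos]])
    if (nrow(win) > 1) {
      win <- win[order(win$start), ]
      if (any(win$start[-1] <= win$end[-nrow(win)])) {
        stop("overlapping snow windows for position ", pos, call. = FALSE)
      }
    }
    if (any(win$end < win$start)) {
      stop("snow window end precedes start for position ", pos, call. = FALSE)
    }
  }
  cfg
}

snow_window_dates <- function(windows) {
  if (length(windows) == 0) {
    return(data.frame(start = as.Date(character()), end = as.Date(character())))
  }
  data.frame(
    start = as.Date(vapply(windows, function(w) w[[1]], "")),
    end   = as.Date(vapply(windows, function(w) w[[2]], ""))
  )
}

#' Campaign configuration for the synthetic generator
#'
#' @param sites List of [site_config()] objects (one or two sites).
#' @param start,end Calendar dates (coercible with `as.Date`) bounding the
#'   campaign, inclusive.
#' @param step_minutes Sampling step; must divide 60 or be a multiple of 30.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   record stream bit for bit.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(sites = list(site_config("NW"), site_config("S")),
                         start = "2016-05-01", end = "2017-06-30",
                         step_minutes = 30, seed = 1L) {
  if (inherits(sites, "site_config")) sites <- list(sites)
  start <- as.Date(start)
  end <- as.Date(end)
  if (end <= start) stop("degenerate date range: end must be after start", call. = FALSE)
  if (!(60 %% step_minutes == 0 || step_minutes %% 30 == 0)) {
    stop("step_minutes must divide 60 or be a multiple of 30", call. = FALSE)
  }
  sites <- lapply(sites, validate_site_config)
  names(sites) <- vapply(sites, function(s) s$site_id, "")
  if (anyDuplicated(names(sites))) stop("duplicate site_id", call. = FALSE)
  structure(
    list(sites = sites, start = start, end = end,
         step_minutes = as.integer(step_minutes), seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Regular campaign time grid (UTC used as a stand-in for local solar time).
campaign_grid <- function(config) {
  t0 <- as.POSIXct(paste(config$start, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(config$end, "23:59:59"), tz = "UTC")
  seq(t0, t1, by = config$step_minutes * 60)
}

# Deterministic open-field air temperature at the given timestamps:
# annual harmonic plus a season-modulated diurnal harmonic peaking at 14:00.
deterministic_open_T <- function(site, timestamps) {
  doy <- as.numeric(lubridate::yday(timestamps))
  hr <- lubridate::hour(timestamps) + lubridate::minute(timestamps) / 60
  seas_arg <- 2 * pi * (doy - site$seasonal_phase) / 365.25
  seasonal <- site$annual_mean_T + site$seasonal_amplitude * cos(seas_arg)
  w <- (1 + cos(seas_arg)) / 2
  amp <- site$diurnal_amplitude_winter +
    (site$diurnal_amplitude_summer - site$diurnal_amplitude_winter) * w
  seasonal + amp * cos(2 * pi * (hr - 14) / 24)
}

# Deterministic below-canopy air temperature (no noise, no random effects).
deterministic_canopy_T <- function(site, timestamps, t_open = NULL) {
  if (is.null(t_open)) t_open <- deterministic_open_T(site, timestamps)
  p <- site$hourly_slope_profile[lubridate::hour(timestamps) + 1L]
  site$coupling_intercept + site$coupling_slope * p * t_open
}
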