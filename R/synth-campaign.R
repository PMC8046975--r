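#' Generate a synthetic paired-station microclimate campaign
#'
#' Simulates half-hourly (or finer) records for each configured site at two
#' positions (`below_canopy`, `open_field`) and four variables (`air_T`,
#' `rh`, `soil_T`, `soil_m`), together with the ground truth implied by the
#' configuration and a log of injected gaps and outlier spikes.
#'
#' The open-field air temperature is an annual harmonic plus a
#' season-modulated diurnal harmonic plus a day-scale synoptic AR(1) state
#' plus stationary within-day AR(1) noise. The
#' below-canopy air temperature couples to the realized open-field series
#' through \eqn{\alpha + \beta p_h T_{out}} with hour-of-day slope
#' multipliers \eqn{p_h}, plus nested month/day/hour random intercepts and
#' independent smaller-variance AR(1) noise. Soil temperature is a lagged,
#' exponentially smoothed copy of the position's air temperature, clamped to
#' within 0.3 degC of zero inside configured snow windows. Soil moisture is
#' event-driven wet-up (shared rain events, reduced below canopy by the
#' interception fraction) with exponential dry-down. Gaps are missing values
#' at the configured rate; outliers are spikes of 8-15 series standard
#' deviations, large enough for a +/-3 SD screen to find.
#'
#' @param config A [synth_config()].
#' @param variables Subset of variables to generate (all four by default).
#' @param truth If `TRUE`, attach the [site_ground_truth] block per site.
#' @param daily_max_reps Monte-Carlo replicates for the expected
#'   daily-maximum offset truth; `0` skips that (slowest) truth entry.
#'
#' @return A list of class `micro_campaign` with elements `records` (tibble:
#'   `timestamp, site, position, variable, value`), `truth` (per-site ground
#'   truth), and `injections` (tibble logging every injected gap/outlier).
#'   Identical configuration and seed give bitwise-identical output.
#' @export
#' @examples
#' cfg <- synth_config(site_config("S", gap_fraction = 0, outlier_fraction = 0),
#'                     end = "2016-06-30", seed = 7)
#' camp <- generate_campaign(cfg, variables = "air_T", daily_max_reps = 0)
#' head(camp$records)
generate_campaign <- function(config,
                              variables = c("air_T", "rh", "soil_T", "soil_m"),
                              truth = TRUE, daily_max_reps = 120) {
  stopifnot(inherits(config, "synth_config"))
  variables <- match.arg(variables, several.ok = TRUE)
  ts <- campaign_grid(config)
  pieces <- with_seed(config$seed, {
    lapply(config$sites, function(site) simulate_site(site, config, ts, variables))
  })
  records <- dplyr::bind_rows(lapply(pieces, `[[`, "records"))
  injections <- dplyr::bind_rows(lapply(pieces, `[[`, "injections"))
  truth_block <- NULL
  if (truth) {
    truth_block <- lapply(config$sites, site_ground_truth, config = config,
                          daily_max_reps = daily_max_reps)
  }
  structure(
    list(records = records, truth = truth_block, injections = injections,
         config = config),
    class = "micro_campaign"
  )
}

simulate_site <- function(site, config, ts, variables) {
  n <- length(ts)
  step <- config$step_minutes
  hr <- lubridate::hour(ts)
  date <- as.Date(ts)
  p <- site$hourly_slope_profile[hr + 1L]

  t_open_det <- deterministic_open_T(site, ts)
  # day-scale synoptic weather state, shared by both positions via the coupling
  udays <- unique(dkey_all <- as.character(date))
  synoptic <- ar1_series(length(udays), site$synoptic_rho, site$synoptic_sd)
  e_open <- synoptic[match(dkey_all, udays)] +
    ar1_series(n, site$ar1_rho, site$ar1_sd)
  e_can <- ar1_series(n, site$ar1_rho, site$canopy_noise_ratio * site$ar1_sd)

  mkey <- month_key(ts)
  dkey <- as.character(date)
  hkey <- paste(dkey, hr)
  re_m <- rnorm(length(unique(mkey)), 0, site$offset_random_sd_month)
  re_d <- rnorm(length(unique(dkey)), 0, site$offset_random_sd_day)
  re_h <- rnorm(length(unique(hkey)), 0, site$offset_random_sd_hour)
  re <- re_m[match(mkey, unique(mkey))] +
    re_d[match(dkey, unique(dkey))] +
    re_h[match(hkey, unique(hkey))]

  t_out <- t_open_det + e_open
  t_in <- site$coupling_intercept + site$coupling_slope * p * t_out + re + e_can

  air <- list(open_field = t_out, below_canopy = t_in)
  series <- list()
  for (pos in c("below_canopy", "open_field")) {
    if ("air_T" %in% variables) series[[paste0(pos, ".air_T")]] <- air[[pos]]
    if ("rh" %in% variables) {
      rh <- 75 - 1.5 * (air[[pos]] - site$annual_mean_T) + rnorm(n, 0, 4)
      series[[paste0(pos, ".rh")]] <- clamp(rh, 0, 100)
    }
    if ("soil_T" %in% variables) {
      series[[paste0(pos, ".soil_T")]] <-
        soil_temperature(air[[pos]], site, config, date)
      series[[paste0(pos, ".soil_T")]] <-
        apply_snow_clamp(series[[paste0(pos, ".soil_T")]], site, pos, date)
    }
  }
  if ("soil_m" %in% variables) {
    event <- runif(n) < site$rain_rate * step / 1440
    size <- runif(n, 0.03, 0.12) * event
    for (pos in c("below_canopy", "open_field")) {
      input <- if (pos == "below_canopy") size * (1 - site$interception_fraction) else size
      series[[paste0(pos, ".soil_m")]] <-
        soil_moisture(input, site$moisture_decay, step)
    }
  }

  # Gap and outlier injection, per (position, variable) series.
  recs <- vector("list", length(series))
  logs <- vector("list", length(series))
  for (i in seq_along(series)) {
    key <- strsplit(names(series)[i], ".", fixed = TRUE)[[1]]
    v <- series[[i]]
    gap <- runif(n) < site$gap_fraction
    out_idx <- which(runif(n) < site$outlier_fraction & !gap)
    spike <- numeric(0)
    if (length(out_idx) > 0) {
      s <- sd(v)
      spike <- v[out_idx] +
        sample(c(-1, 1), length(out_idx), replace = TRUE) *
          runif(length(out_idx), 8, 15) * s
    }
    v[gap] <- NA_real_
    v[out_idx] <- spike
    recs[[i]] <- tibble::tibble(
      timestamp = ts, site = site$site_id, position = key[1],
      variable = key[2], value = v
    )
    logs[[i]] <- tibble::tibble(
      timestamp = c(ts[gap], ts[out_idx]),
      site = site$site_id, position = key[1], variable = key[2],
      kind = c(rep("gap", sum(gap)), rep("outlier", length(out_idx))),
      injected_value = c(rep(NA_real_, sum(gap)), spike)
    )
  }
  list(records = dplyr::bind_rows(recs), injections = dplyr::bind_rows(logs))
}

# Lagged, exponentially smoothed copy of air temperature.
soil_temperature <- function(t_air, site, config, date) {
  lag_steps <- round(site$soil_lag * 60 / config$step_minutes)
  lagged <- dplyr::lag(t_air, lag_steps, default = t_air[1])
  k <- site$soil_damping
  as.numeric(stats::filter(k * lagged, 1 - k, method = "recursive",
                           init = lagged[1]))
}

# Inside snow windows soil temperature sits within 0.3 degC of zero
# (zero-curtain under an insulating snowpack).
apply_snow_clamp <- function(soil, site, position, date) {
  win <- snow_window_dates(site$snow_windows[[position]])
  if (nrow(win) == 0) return(soil)
  in_win <- rep(FALSE, length(date))
  for (i in seq_len(nrow(win))) {
    in_win <- in_win | (date >= win$start[i] & date <= win$end[i])
  }
  soil[in_win] <- clamp(rnorm(sum(in_win), 0, 0.1), -0.3, 0.3)
  soil
}

# Event-driven wet-up with exponential dry-down toward a residual content.
soil_moisture <- function(input, decay_per_day, step_minutes,
                          residual = 0.08, m0 = 0.15, cap = 0.55) {
  d <- exp(-decay_per_day * step_minutes / 1440)
  n <- length(input)
  m <- numeric(n)
  state <- m0
  for (i in seq_len(n)) {
    state <- residual + d * (state - residual) + input[i]
    if (state > cap) state <- cap
    m[i] <- state
  }
  m
}

#' Generate a 16-day NDVI composite series with known phenology
#'
#' A double-logistic seasonal curve whose half-amplitude upward and downward
#' crossings sit exactly at `sos` and `eos`, sampled on the standard 23
#' composite dates per year, with optional Gaussian noise.
#'
#' @param sos,eos Start/end of season, day-of-year, `0 < sos < eos <= 366`.
#' @param base Dormant-season NDVI level.
#' @param amplitude Seasonal amplitude (> 0); `base + amplitude` must stay
#'   within \[-1, 1\].
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed for the noise.
#' @param steepness Logistic transition scale in days.
#' @return Tibble with `doy` and `ndvi` (23 rows).
#' @export
generate_ndvi_series <- function(sos, eos, base = 0.25, amplitude = 0.45,
                                 noise_sd = 0, seed = 1L, steepness = 4) {
  if (amplitude <= 0) stop("amplitude must be positive", call. = FALSE)
  if (!(sos > 0 && sos < eos && eos <= 366)) {
    stop("need 0 < sos < eos <= 366", call. = FALSE)
  }
  if (base < -1 || base > 1 || base + amplitude < -1 || base + amplitude > 1) {
    stop("base and base + amplitude must lie in [-1, 1]", call. = FALSE)
  }
  doy <- seq(1, 353, by = 16)
  curve <- base + amplitude *
    (stats::plogis((doy - sos) / steepness) -
       stats::plogis((doy - eos) / steepness))
  ndvi <- with_seed(seed, curve + rnorm(length(doy), 0, noise_sd))
  tibble::tibble(doy = doy, ndvi = ndvi)
}
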