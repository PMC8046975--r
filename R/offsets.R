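#' Pairwise temperature (or moisture) offset series
#'
#' Offset = below-canopy minus open-field value at matched timestamps,
#' defined only where both positions carry a non-flagged (`"ok"`) value;
#' unmatched or flagged slots are skipped (their count is attached as the
#' `n_skipped` attribute). Negative offsets mean cooler below the canopy.
#'
#' @param below,open Screened tibbles (see [screen_outliers()]) for the two
#'   positions of one or more sites/variables.
#' @return Tibble with `site, variable, timestamp, delta`.
#' @export
compute_offset_series <- function(below, open) {
  b <- flagged_cols(below)
  o <- flagged_cols(open)
  joined <- dplyr::inner_join(b, o, by = c("site", "variable", "timestamp"),
                              suffix = c("_below", "_open"))
  if (nrow(joined) == 0) stop("disjoint grids: no matched timestamps", call. = FALSE)
  ok <- joined$qc_flag_below == "ok" & joined$qc_flag_open == "ok"
  n_skipped <- nrow(b) + nrow(o) - 2 * sum(ok)
  out <- joined |>
    dplyr::filter(ok) |>
    dplyr::transmute(.data$site, .data$variable, .data$timestamp,
                     delta = .data$value_below - .data$value_open)
  attr(out, "n_skipped") <- n_skipped
  out
}

flagged_cols <- function(df) {
  if (!"qc_flag" %in% names(df)) {
    df$qc_flag <- ifelse(is.na(df$value), "gap", "ok")
  }
  dplyr::select(df, "site", "variable", "timestamp", "value", "qc_flag")
}

#' Seasonal offset estimates under nested random intercepts
#'
#' The headline offset statistics per site and season. The `mean` statistic
#' fits the intercept-only model with nested month/day/hour random
#' intercepts to the half-hourly offsets. `daily_max` and `daily_min` first
#' reduce each position to daily extremes (difference of per-day extremes,
#' not extreme of differences), then fit month-level random intercepts to
#' the daily offsets (with one value per day, the day level is the
#' residual). Negative estimates mean cooler below the canopy.
#'
#' @param below,open Screened tibbles for the two positions (one variable,
#'   e.g. `air_T`; multiple sites allowed).
#' @param seasons Character subset of `"JJA"`, `"DJF"`, `"GS"`.
#' @param statistics Character subset of `"mean"`, `"daily_max"`,
#'   `"daily_min"`.
#' @param min_completeness Daily completeness threshold for the extreme
#'   statistics.
#' @param min_days Minimum days of paired data a season must hold.
#' @return Tibble with one row per site x season x statistic: `mu`, `se`,
#'   `n`, and variance components `sigma2_month`, `sigma2_day`,
#'   `sigma2_hour`, `sigma2_resid`.
#' @export
seasonal_offset_table <- function(below, open,
                                  seasons = c("JJA", "DJF", "GS"),
                                  statistics = c("mean", "daily_max", "daily_min"),
                                  min_completeness = 0.9, min_days = 14) {
  seasons <- match.arg(seasons, several.ok = TRUE)
  statistics <- match.arg(statistics, several.ok = TRUE)
  deltas <- compute_offset_series(below, open)
  daily <- NULL
  if (any(statistics %in% c("daily_max", "daily_min"))) {
    agg <- dplyr::bind_rows(
      aggregate_series(below, "day", min_completeness),
      aggregate_series(open, "day", min_completeness)
    )
    daily <- agg |>
      tidyr::pivot_wider(id_cols = c("site", "variable", "bin_start"),
                         names_from = "position",
                         values_from = c("min", "max"))
  }
  out <- list()
  for (site_id in unique(deltas$site)) {
    for (season in seasons) {
      for (statistic in statistics) {
        est <- tryCatch(
          one_offset_estimate(deltas, daily, site_id, season, statistic,
                              min_days),
          error = function(e) stop("site ", site_id, ", ", season, " ",
                                   statistic, ": ", conditionMessage(e),
                                   call. = FALSE)
        )
        out[[length(out) + 1]] <- est
      }
    }
  }
  dplyr::bind_rows(out)
}

one_offset_estimate <- function(deltas, daily, site_id, season, statistic,
                                min_days) {
  if (statistic == "mean") {
    d <- select_season(dplyr::filter(deltas, .data$site == site_id), season)
    if (length(unique(as.Date(d$timestamp))) < min_days) {
      stop("season holds fewer than ", min_days, " days of paired data")
    }
    vc <- fit_nested_intercept_model(
      d$delta,
      month = month_key(d$timestamp),
      day = as.character(as.Date(d$timestamp)),
      hour = lubridate::hour(d$timestamp)
    )
  } else {
    col <- if (statistic == "daily_max") "max" else "min"
    d <- daily |>
      dplyr::filter(.data$site == site_id) |>
      dplyr::transmute(
        .data$site, .data$bin_start,
        delta = .data[[paste0(col, "_below_canopy")]] -
          .data[[paste0(col, "_open_field")]]
      ) |>
      dplyr::filter(!is.na(.data$delta))
    d <- select_season(d, season)
    if (nrow(d) < min_days) {
      stop("season holds fewer than ", min_days, " days of paired data")
    }
    # one observation per day: the day level is the residual variance
    vc <- fit_nested_intercept_model(d$delta, month = month_key(d$bin_start))
    vc$sigma2[["day"]] <- vc$sigma2[["resid"]]
  }
  tibble::tibble(
    site = site_id, season = season, statistic = statistic,
    mu = vc$mu, se = vc$se_mu, n = vc$n,
    sigma2_month = vc$sigma2[["month"]], sigma2_day = vc$sigma2[["day"]],
    sigma2_hour = vc$sigma2[["hour"]], sigma2_resid = vc$sigma2[["resid"]]
  )
}

#' Hourly coupling profile of below-canopy on open-field temperature
#'
#' For each hour of day, the OLS slope of below-canopy on open-field
#' temperature across the season's paired records (half-hourly records are
#' pooled within the hour). An hour is flagged decoupled when the slope
#' point estimate falls below `slope_threshold` *and* the upper confidence
#' bound stays below `ci_upper_threshold` (i.e. the canopy demonstrably
#' tracks the open field at less than one-to-one); otherwise it is coupled.
#' Hours with fewer than `min_pairs` pairs are reported with `NA` and a
#' missing flag rather than an error.
#'
#' @param below,open Screened tibbles for one site/variable.
#' @param season Season to pool over (default growing season).
#' @param slope_threshold,ci_upper_threshold Decoupling rule parameters.
#' @param min_pairs Minimum paired observations per hour.
#' @param conf Confidence level of the slope interval.
#' @return Tibble with `hour, slope, se, ci_lo, ci_hi, n, coupled`.
#' @export
hourly_coupling_profile <- function(below, open, season = "GS",
                                    slope_threshold = 0.8,
                                    ci_upper_threshold = 1,
                                    min_pairs = 30, conf = 0.95) {
  b <- flagged_cols(below)
  o <- flagged_cols(open)
  pairs <- dplyr::inner_join(b, o, by = c("site", "variable", "timestamp"),
                             suffix = c("_below", "_open")) |>
    dplyr::filter(.data$qc_flag_below == "ok", .data$qc_flag_open == "ok")
  pairs <- select_season(pairs, season)
  pairs$hour <- lubridate::hour(pairs$timestamp)
  out <- lapply(0:23, function(h) {
    d <- pairs[pairs$hour == h, ]
    if (nrow(d) < min_pairs || var(d$value_open) == 0) {
      return(tibble::tibble(hour = h, slope = NA_real_, se = NA_real_,
                            ci_lo = NA_real_, ci_hi = NA_real_,
                            n = nrow(d), coupled = NA))
    }
    f <- fit_line_ols(d$value_open, d$value_below)
    tq <- qt(1 - (1 - conf) / 2, f$n - 2)
    ci <- f$beta + c(-1, 1) * tq * f$se_beta
    tibble::tibble(
      hour = h, slope = f$beta, se = f$se_beta,
      ci_lo = ci[1], ci_hi = ci[2], n = f$n,
      coupled = !(f$beta < slope_threshold & ci[2] < ci_upper_threshold)
    )
  })
  dplyr::bind_rows(out)
}
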