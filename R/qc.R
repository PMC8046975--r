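#' Screen outliers with a +/-3 SD rule
#'
#' For every (site, position, variable) series, values outside
#' `mean +/- 3 SD` -- with mean and SD computed once on the full raw record
#' -- are flagged `"outlier"`; missing values are flagged `"gap"`, the rest
#' `"ok"`. Flagged outliers are excluded from all downstream statistics. The
#' screen is a single pass: an already-screened input (one that carries a
#' `qc_flag` column) is returned unchanged, so screening is idempotent and
#' the mean/SD are never recomputed on a trimmed record.
#'
#' @param records Tibble with columns `timestamp, site, position, variable,
#'   value` (a `qc_flag` column marks it as already screened).
#' @param k SD multiplier of the screen (default 3).
#' @return The input with a `qc_flag` column (`"ok"|"outlier"|"gap"`).
#' @export
screen_outliers <- function(records, k = 3) {
  if ("qc_flag" %in% names(records)) {
    return(records)
  }
  flagged <- records |>
    dplyr::group_by(.data$site, .data$position, .data$variable) |>
    dplyr::group_modify(function(df, key) {
      v <- df$value
      n_ok <- sum(!is.na(v))
      if (n_ok == 0) {
        stop("all-missing series: ", paste(key, collapse = "/"), call. = FALSE)
      }
      if (n_ok < 10) {
        stop("need >= 10 non-missing values to screen: ",
             paste(key, collapse = "/"), call. = FALSE)
      }
      m <- mean(v, na.rm = TRUE)
      s <- sd(v, na.rm = TRUE)
      df$qc_flag <- dplyr::case_when(
        is.na(v) ~ "gap",
        abs(v - m) > k * s ~ "outlier",
        TRUE ~ "ok"
      )
      df
    }) |>
    dplyr::ungroup()
  dplyr::relocate(flagged, names(records)[names(records) != "qc_flag"])
}

#' Aggregate a cleaned series to half-hourly, daily or ISO-week bins
#'
#' Arithmetic mean, min and max over non-flagged values per bin; bins whose
#' completeness (fraction of expected grid slots with an `"ok"` value) falls
#' below `min_completeness` emit missing summaries. The expected slot count
#' per bin is derived from the grid step, inferred as the median timestamp
#' spacing per series.
#'
#' @param clean Screened tibble from [screen_outliers()] (an unscreened
#'   tibble is accepted: missing values become gaps, everything else `ok`).
#' @param period `"day"`, `"iso_week"` or `"halfhour"`.
#' @param min_completeness Completeness threshold in \[0, 1\] below which a
#'   bin's statistics are set to `NA` (default 0.9, guarding daily min/max
#'   against gap bias).
#' @return Tibble with `site, position, variable, bin_start, mean, min, max,
#'   n_ok, completeness`. `bin_start` is a `Date` for daily bins, the ISO
#'   week's Monday for weekly bins, and a `POSIXct` for half-hour bins.
#' @export
aggregate_series <- function(clean, period = c("day", "iso_week", "halfhour"),
                             min_completeness = 0.9) {
  period <- match.arg(period)
  if (!"qc_flag" %in% names(clean)) {
    clean$qc_flag <- ifelse(is.na(clean$value), "gap", "ok")
  }
  binned <- clean |>
    dplyr::group_by(.data$site, .data$position, .data$variable) |>
    dplyr::group_modify(function(df, key) {
      step_min <- infer_step_minutes(df$timestamp)
      bin <- switch(period,
        day = as.Date(df$timestamp),
        iso_week = lubridate::floor_date(as.Date(df$timestamp), "week",
                                         week_start = 1),
        halfhour = lubridate::floor_date(df$timestamp, "30 minutes")
      )
      expected <- switch(period,
        day = 1440 / step_min,
        iso_week = 7 * 1440 / step_min,
        halfhour = max(1, 30 / step_min)
      )
      ok <- df$qc_flag == "ok"
      out <- tibble::tibble(bin_start = bin, value = ifelse(ok, df$value, NA)) |>
        dplyr::group_by(.data$bin_start) |>
        dplyr::summarise(
          n_ok = sum(!is.na(.data$value)),
          mean = mean(.data$value, na.rm = TRUE),
          min = suppressWarnings(min(.data$value, na.rm = TRUE)),
          max = suppressWarnings(max(.data$value, na.rm = TRUE)),
          .groups = "drop"
        ) |>
        dplyr::mutate(completeness = .data$n_ok / expected)
      low <- out$completeness < min_completeness | out$n_ok == 0
      out$mean[low] <- NA_real_
      out$min[low] <- NA_real_
      out$max[low] <- NA_real_
      out$min[is.infinite(out$min)] <- NA_real_
      out$max[is.infinite(out$max)] <- NA_real_
      dplyr::select(out, "bin_start", "mean", "min", "max", "n_ok",
                    "completeness")
    }) |>
    dplyr::ungroup()
  binned
}

infer_step_minutes <- function(timestamps) {
  d <- diff(as.numeric(sort(unique(timestamps)))) / 60
  if (length(d) == 0) return(30)
  median(d)
}

#' Restrict records or summaries to a climatological season
#'
#' `GS` (growing season) is May 1 to Sep 30 inclusive, `JJA` June-August and
#' `DJF` December-February; `DJF` naturally spans the year boundary
#' (December of one year with the following January/February).
#'
#' @param x Tibble with a `timestamp`, `bin_start` or `date` column.
#' @param season `"JJA"`, `"DJF"`, `"GS"`, or `"custom"`.
#' @param months Integer months 1-12 when `season = "custom"`.
#' @return The filtered tibble; an empty selection is an error.
#' @export
select_season <- function(x, season = c("GS", "JJA", "DJF", "custom"),
                          months = NULL) {
  season <- match.arg(season)
  mon <- if (season == "custom") {
    if (is.null(months)) stop("custom season needs `months`", call. = FALSE)
    as.integer(months)
  } else {
    season_months(season)
  }
  col <- intersect(c("timestamp", "bin_start", "date"), names(x))[1]
  if (is.na(col)) stop("no timestamp/bin_start/date column", call. = FALSE)
  out <- dplyr::filter(x, lubridate::month(.data[[col]]) %in% mon)
  if (nrow(out) == 0) stop("empty season selection: ", season, call. = FALSE)
  out
}
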