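#' Detect snow periods from daily soil-temperature summaries
#'
#' Under an insulating snowpack the soil sits in a zero-curtain: daily mean
#' soil temperature close to 0 degC with very small diurnal amplitude. A day
#' is a snow candidate when its mean lies in `mean_range` and its amplitude
#' (max - min) is below `max_amplitude`; runs of at least `min_run`
#' consecutive candidate days become snow periods.
#'
#' @param daily Daily summaries from [aggregate_series()] for `soil_T`
#'   (single site/position).
#' @param mean_range Candidate window for the daily mean, degC.
#' @param max_amplitude Candidate ceiling for the daily amplitude, degC.
#' @param min_run Minimum run length in days.
#' @return Tibble with `start`, `end` (Dates), `days`.
#' @export
detect_snow_periods <- function(daily, mean_range = c(-0.5, 1.5),
                                max_amplitude = 1.0, min_run = 3) {
  d <- daily[order(daily$bin_start), ]
  cand <- !is.na(d$mean) & !is.na(d$min) & !is.na(d$max) &
    d$mean >= mean_range[1] & d$mean <= mean_range[2] &
    (d$max - d$min) < max_amplitude
  if (!any(cand)) {
    return(tibble::tibble(start = as.Date(character()),
                          end = as.Date(character()), days = integer()))
  }
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  tibble::tibble(
    start = as.Date(d$bin_start[starts[keep]]),
    end = as.Date(d$bin_start[ends[keep]]),
    days = r$lengths[keep]
  )
}

#' Daily thermal amplitude and window summary
#'
#' Amplitude = daily max - daily min; days missing either extreme are
#' skipped. Returns the per-day series together with the window maximum and
#' mean.
#'
#' @param daily Daily summaries from [aggregate_series()] (single series).
#' @param window Optional Date vector `c(start, end)` restricting the days.
#' @return List with `daily` (tibble `date, amplitude`), `max`, `mean`.
#' @export
thermal_amplitude <- function(daily, window = NULL) {
  d <- daily
  if (!is.null(window)) {
    d <- d[as.Date(d$bin_start) >= as.Date(window[1]) &
             as.Date(d$bin_start) <= as.Date(window[2]), ]
  }
  amp <- d$max - d$min
  keep <- !is.na(amp)
  out <- tibble::tibble(date = as.Date(d$bin_start[keep]),
                        amplitude = amp[keep])
  list(daily = out,
       max = if (nrow(out)) max(out$amplitude) else NA_real_,
       mean = if (nrow(out)) mean(out$amplitude) else NA_real_)
}

#' Growing-season phenology metrics from an NDVI series
#'
#' Smooths the 16-day NDVI composites with local polynomial regression,
#' takes the dormant-season (December-February composites) mean as the
#' baseline and the seasonal maximum as the peak, and locates the start
#' (SOS) and end (EOS) of the growing season as the first upward and last
#' downward crossings of `baseline + threshold_fraction * amplitude`,
#' interpolated linearly between composite dates. LOS = EOS - SOS.
#'
#' @param ndvi Tibble with `doy` and `ndvi` covering at least one full year
#'   of 16-day composites.
#' @param threshold_fraction Fraction of the amplitude above baseline that
#'   defines the season (default 0.5, the half-amplitude convention).
#' @param span Loess span for smoothing.
#' @param min_amplitude Seasonal amplitudes below this are rejected as
#'   having no seasonal signal.
#' @return An object of class `phenology_metrics`: `sos`, `eos` (day of
#'   year), `los` (days, identically `eos - sos`), plus `baseline`, `peak`,
#'   `threshold`.
#' @export
extract_phenology <- function(ndvi, threshold_fraction = 0.5, span = 0.35,
                              min_amplitude = 0.05) {
  stopifnot(all(c("doy", "ndvi") %in% names(ndvi)))
  ndvi <- ndvi[order(ndvi$doy), ]
  if (nrow(ndvi) < 20) stop("need at least one full year of 16-day composites",
                            call. = FALSE)
  sm <- loess(ndvi ~ doy, data = ndvi, span = span, degree = 2)
  grid <- data.frame(doy = seq(min(ndvi$doy), max(ndvi$doy), by = 1))
  curve <- predict(sm, newdata = grid)
  dormant <- ndvi$doy >= 335 | ndvi$doy <= 59
  baseline <- mean(predict(sm, newdata = data.frame(doy = ndvi$doy[dormant])))
  peak <- max(curve)
  amplitude <- peak - baseline
  if (!is.finite(amplitude) || amplitude < min_amplitude) {
    stop("no seasonal NDVI signal (amplitude < ", min_amplitude, ")",
         call. = FALSE)
  }
  thr <- baseline + threshold_fraction * amplitude
  above <- curve >= thr
  up <- which(diff(above) == 1)    # index before the upward crossing
  down <- which(diff(above) == -1) # index before the downward crossing
  if (length(up) == 0 || length(down) == 0) {
    stop("threshold is never crossed in both directions", call. = FALSE)
  }
  cross_at <- function(i) {
    x0 <- grid$doy[i]; x1 <- grid$doy[i + 1]
    y0 <- curve[i]; y1 <- curve[i + 1]
    x0 + (thr - y0) / (y1 - y0) * (x1 - x0)
  }
  sos <- cross_at(up[1])
  eos <- cross_at(down[length(down)])
  if (!(sos < eos)) stop("degenerate phenology: SOS >= EOS", call. = FALSE)
  structure(
    list(sos = sos, eos = eos, los = eos - sos,
         baseline = baseline, peak = peak, threshold = thr),
    class = "phenology_metrics"
  )
}

#' @export
print.phenology_metrics <- function(x, ...) {
  cat(sprintf("Phenology: SOS %.1f, EOS %.1f, LOS %.1f days\n",
              x$sos, x$eos, x$los))
  invisible(x)
}
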