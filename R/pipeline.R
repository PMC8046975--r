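#' Run the full buffering-analysis pipeline
#'
#' Orchestrates simulate (or load) -> QC -> offsets -> coupling/buffering ->
#' soil/snow -> phenology, and returns a machine-readable report. With an
#' `output_dir` the report is written as `report.json` plus per-table CSVs
#' and a plain-text QC log. Reports contain no wall-clock timestamps, so a
#' rerun with the same configuration and seed reproduces them byte for byte.
#'
#' @param config Either a run-configuration list (see [read_run_config()]),
#'   a path to a YAML run configuration, or a [synth_config()].
#' @param output_dir Optional output directory (created if missing).
#' @return A report list with elements `qc`, `group_comparison`, `offsets`,
#'   `offset_response`, `coupling`, `soil`, `phenology`, `site_comparison`,
#'   and `meta`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1) config <- read_run_config(config)
  if (inherits(config, "synth_config")) config <- list(synth_config = config)
  seasons <- config$seasons %||% c("JJA", "DJF", "GS")
  seed <- config$seed %||% (if (!is.null(config$synth_config)) config$synth_config$seed else 1L)
  coupling_rule <- config$coupling %||% list()
  truth <- NULL

  if (!is.null(config$input_csv)) {
    records <- read_campaign_csv(config$input_csv)
  } else if (!is.null(config$synth_config)) {
    camp <- generate_campaign(config$synth_config, daily_max_reps = 0)
    records <- camp$records
    truth <- camp$truth
  } else {
    stop("config must name an input_csv or carry a synth_config", call. = FALSE)
  }
  required <- c("air_T", "soil_T")
  missing_vars <- setdiff(required, unique(records$variable))
  if (length(missing_vars) > 0) {
    stop("missing required variable(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }

  clean <- screen_outliers(records)
  qc_log <- clean |>
    dplyr::group_by(.data$site, .data$position, .data$variable) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_ok = sum(.data$qc_flag == "ok"),
      n_gap = sum(.data$qc_flag == "gap"),
      n_outlier = sum(.data$qc_flag == "outlier"),
      .groups = "drop"
    )

  sites <- unique(clean$site)
  air <- dplyr::filter(clean, .data$variable == "air_T")
  soil_t <- dplyr::filter(clean, .data$variable == "soil_T")
  daily_air <- aggregate_series(air, "day")
  daily_soil <- aggregate_series(soil_t, "day")

  # Growing-season daily means compared across site x position groups.
  group_comparison <- lapply(
    stats::setNames(list(daily_air, daily_soil), c("air_T", "soil_T")),
    function(d) {
      gs <- select_season(dplyr::filter(d, !is.na(.data$mean)), "GS")
      at <- anova_tukey(gs$mean, paste(gs$site, gs$position, sep = "_"))
      list(f = at$f, p = at$p, letters = as.list(at$letters),
           group_means = as.list(tapply(gs$mean,
                                        paste(gs$site, gs$position, sep = "_"),
                                        mean)))
    })

  below <- dplyr::filter(air, .data$position == "below_canopy")
  open <- dplyr::filter(air, .data$position == "open_field")
  offsets <- seasonal_offset_table(below, open, seasons = seasons)

  per_site <- lapply(stats::setNames(sites, sites), function(s) {
    b <- dplyr::filter(below, .data$site == s)
    o <- dplyr::filter(open, .data$site == s)
    resp <- offset_response(b, o)
    cpl <- coupling_analysis(b, o, coupling_rule)
    soil_s <- soil_summaries(dplyr::filter(daily_soil, .data$site == s))
    list(offset_response = resp, coupling = cpl, soil = soil_s)
  })

  phenology <- NULL
  if (!is.null(config$ndvi_csv)) {
    ph <- extract_phenology(read_ndvi_csv(config$ndvi_csv))
    phenology <- list(overall = unclass(ph)[c("sos", "eos", "los")])
  } else if (!is.null(truth)) {
    phenology <- lapply(truth, function(tr) {
      ndvi <- generate_ndvi_series(tr$sos, tr$eos, noise_sd = 0.02,
                                   seed = seed + 7L)
      unclass(extract_phenology(ndvi))[c("sos", "eos", "los")]
    })
  }

  site_comparison <- NULL
  if (length(sites) >= 2) {
    pairs <- dplyr::bind_rows(lapply(sites, function(s) {
      per_site[[s]]$coupling$daily_pairs |> dplyr::mutate(site = s)
    }))
    cmp <- compare_buffering(pairs)
    site_comparison <- list(slope_diff = cmp$slope_diff,
                            intercept_diff = cmp$intercept_diff)
  }

  report <- list(
    meta = list(seed = seed, seasons = seasons, sites = as.list(sites)),
    qc = qc_log,
    group_comparison = group_comparison,
    offsets = offsets,
    per_site = lapply(per_site, report_site_block),
    site_comparison = site_comparison,
    phenology = phenology,
    truth = truth
  )
  if (!is.null(output_dir)) write_report(report, per_site, output_dir)
  invisible(report)
}

# Offset-response during the growing season: harmonic mixed line of the
# offset on open-field temperature, chi-squared comparison against the
# intercept-only baseline, and a penalized-spline nonlinearity check on the
# partial residuals (random-effect BLUPs and harmonics absorbed).
offset_response <- function(below, open, season = "GS") {
  deltas <- select_season(compute_offset_series(below, open), season)
  o <- flagged_cols(open)
  d <- dplyr::inner_join(
    deltas, dplyr::select(o, "site", "variable", "timestamp", "value"),
    by = c("site", "variable", "timestamp")
  )
  hour <- lubridate::hour(d$timestamp)
  month <- month_key(d$timestamp)
  day <- as.character(as.Date(d$timestamp))
  mix <- fit_mixed_line(d$delta, d$value, hour, month, day)
  null_model <- fit_nested_intercept_model(d$delta, month, day)
  lrt <- lrt_compare(mix, null_model)
  partial <- d$delta - predict(mix$model) +
    mix$beta[1] + mix$beta[2] * d$value
  spl <- fit_penalized_spline(partial, d$value)
  list(mixed = mix, spline = spl, lrt = lrt)
}

# Growing-season daily-mean coupling line, buffering capacity over the
# observed open-field range, and the hourly decoupling profile.
coupling_analysis <- function(below, open, rule = list()) {
  db <- aggregate_series(below, "day")
  do <- aggregate_series(open, "day")
  pairs <- dplyr::inner_join(
    dplyr::select(db, "bin_start", t_in = "mean"),
    dplyr::select(do, "bin_start", t_out = "mean"),
    by = "bin_start"
  ) |> dplyr::filter(!is.na(.data$t_in), !is.na(.data$t_out))
  pairs_gs <- select_season(pairs, "GS")
  fit <- fit_line_ols(pairs_gs$t_out, pairs_gs$t_in)
  buff <- buffering_capacity(fit, min(pairs_gs$t_out), max(pairs_gs$t_out))
  hourly <- hourly_coupling_profile(
    below, open,
    slope_threshold = rule$slope_threshold %||% 0.8,
    ci_upper_threshold = rule$ci_upper_threshold %||% 1
  )
  list(fit = fit, buffering = buff, hourly = hourly, daily_pairs = pairs_gs)
}

soil_summaries <- function(daily_soil_site) {
  out <- lapply(split(daily_soil_site, daily_soil_site$position), function(d) {
    snow <- detect_snow_periods(d)
    amp <- thermal_amplitude(d)
    list(
      snow_periods = snow,
      amplitude_max = amp$max,
      amplitude_mean = amp$mean
    )
  })
  out
}

report_site_block <- function(ps) {
  list(
    offset_response = list(
      intercept = unname(ps$offset_response$mixed$beta[1]),
      slope = unname(ps$offset_response$mixed$beta[2]),
      slope_se = unname(ps$offset_response$mixed$se[2]),
      r2m = ps$offset_response$mixed$r2m,
      r2c = ps$offset_response$mixed$r2c,
      lrt_chisq = ps$offset_response$lrt$chisq,
      lrt_p = ps$offset_response$lrt$p,
      spline_edf = ps$offset_response$spline$edf
    ),
    coupling = list(
      alpha = ps$coupling$fit$alpha, beta = ps$coupling$fit$beta,
      se_alpha = ps$coupling$fit$se_alpha, se_beta = ps$coupling$fit$se_beta,
      x_star = ps$coupling$buffering$x_star,
      x_min = ps$coupling$buffering$x_min,
      x_max = ps$coupling$buffering$x_max,
      b_warm = ps$coupling$buffering$b_warm,
      b_cool = ps$coupling$buffering$b_cool,
      hourly = ps$coupling$hourly
    ),
    soil = lapply(ps$soil, function(x) {
      list(amplitude_max = x$amplitude_max, amplitude_mean = x$amplitude_mean,
           snow_periods = x$snow_periods)
    })
  )
}

write_report <- function(report, per_site, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    report[setdiff(names(report), "truth")],
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = 10, pretty = TRUE, dataframe = "rows",
    na = "null"
  )
  if (!is.null(report$truth)) {
    jsonlite::write_json(report$truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         na = "null")
  }
  readr::write_csv(report$offsets, file.path(dir, "offsets.csv"))
  readr::write_csv(report$qc, file.path(dir, "qc_summary.csv"))
  for (s in names(per_site)) {
    readr::write_csv(per_site[[s]]$coupling$hourly,
                     file.path(dir, paste0("hourly_coupling_", s, ".csv")))
    readr::write_csv(per_site[[s]]$coupling$daily_pairs,
                     file.path(dir, paste0("daily_pairs_", s, ".csv")))
  }
  log_lines <- c(
    "QC log: +/-3 SD screen on the full record per (site, position, variable)",
    utils::capture.output(print(as.data.frame(report$qc)))
  )
  writeLines(log_lines, file.path(dir, "qc_log.txt"))
  invisible(dir)
}
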