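#' Read and write campaign record CSVs
#'
#' The CSV dialect is `timestamp,site,position,variable,value` with ISO 8601
#' timestamps (UTC, standing in for local solar time).
#'
#' @param path File path.
#' @return `read_campaign_csv()` returns the records tibble.
#' @export
read_campaign_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_datetime(),
    site = readr::col_character(),
    position = readr::col_character(),
    variable = readr::col_character(),
    value = readr::col_double()
  ))
}

#' @param records Records tibble (or a `micro_campaign`).
#' @rdname read_campaign_csv
#' @export
write_campaign_csv <- function(records, path) {
  if (inherits(records, "micro_campaign")) records <- records$records
  out <- records
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ")
  readr::write_csv(out[c("timestamp", "site", "position", "variable", "value")],
                   path, na = "")
  invisible(path)
}

#' Read an NDVI CSV (`date,ndvi` or `doy,ndvi`)
#' @param path File path.
#' @return Tibble with `doy` and `ndvi`.
#' @export
read_ndvi_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols())
  if ("date" %in% names(df) && !"doy" %in% names(df)) {
    df$doy <- lubridate::yday(as.Date(df$date))
  }
  tibble::as_tibble(df[c("doy", "ndvi")])
}

#' Read a pipeline run configuration from YAML
#'
#' The file either names an `input_csv` of station records or carries a
#' `synth:` block (start/end/step_minutes and per-site overrides) for the
#' generator; exactly one source must be present. Optional keys: `seed`,
#' `seasons`, `output_dir`, `coupling: {slope_threshold, ci_upper_threshold}`,
#' `ndvi_csv`.
#'
#' @param path YAML file path.
#' @return A run-configuration list accepted by [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$input_csv) && is.null(cfg$synth)) {
    stop("run config needs either input_csv or a synth block", call. = FALSE)
  }
  if (!is.null(cfg$synth)) {
    sites <- lapply(cfg$synth$sites %||% list(list(site_id = "NW"), list(site_id = "S")),
                    function(s) do.call(site_config, s))
    cfg$synth_config <- synth_config(
      sites = sites,
      start = cfg$synth$start %||% "2016-05-01",
      end = cfg$synth$end %||% "2017-06-30",
      step_minutes = cfg$synth$step_minutes %||% 30,
      seed = cfg$seed %||% 1L
    )
  }
  cfg
}
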