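#' Simulate one campaign and recover a seasonal offset estimate
#'
#' Parameter-recovery harness used to validate the estimators against the
#' generator's ground truth: generates one single-site air-temperature
#' campaign, runs the QC screen, computes offsets, and fits the seasonal
#' offset estimator.
#'
#' @param site A [site_config()] (typically calibrated so a chosen truth
#'   equals a target value).
#' @param seed Campaign seed.
#' @param season,statistic Passed to [seasonal_offset_table()].
#' @param start,end Campaign date range (default one year, May to April).
#' @return One-row tibble: `mu`, `se`, `n`.
#' @export
recover_seasonal_offset <- function(site, seed, season = "GS",
                                    statistic = "mean",
                                    start = "2016-05-01", end = "2017-04-30") {
  cfg <- synth_config(list(site), start = start, end = end, seed = seed)
  camp <- generate_campaign(cfg, variables = "air_T", truth = FALSE)
  clean <- screen_outliers(camp$records)
  below <- dplyr::filter(clean, .data$position == "below_canopy")
  open <- dplyr::filter(clean, .data$position == "open_field")
  tab <- seasonal_offset_table(below, open, seasons = season,
                               statistics = statistic)
  tab[c("mu", "se", "n")]
}

#' Simulate one campaign and recover the daily-mean coupling slope
#'
#' Generates a single-site campaign, aggregates to growing-season daily
#' means, and fits the OLS coupling line of below-canopy on open-field
#' temperature.
#'
#' @details
#' The slope is the plain OLS estimate on daily means. Its standard error,
#' however, is not the iid OLS formula: the generator places a random
#' intercept on each month, so daily means within a month share an error
#' component that is correlated with the seasonal trend in the predictor.
#' The reported `se_beta` is the OLS sampling standard error under that
#' error structure, \eqn{\sqrt{\sigma^2_r / \sum d_i^2 + \sigma^2_m \sum_m
#' a_m^2}} with \eqn{d_i} the predictor deviations and \eqn{a_m} the
#' month-summed deviation weights, using month and residual variance
#' components estimated by REML on the same daily means.
#'
#' @inheritParams recover_seasonal_offset
#' @param season Season of daily means to regress over.
#' @return One-row tibble: `alpha`, `beta`, `se_alpha`, `se_beta`, `n`.
#' @export
recover_coupling_slope <- function(site, seed, season = "GS",
                                   start = "2016-05-01", end = "2017-04-30") {
  cfg <- synth_config(list(site), start = start, end = end, seed = seed)
  camp <- generate_campaign(cfg, variables = "air_T", truth = FALSE)
  clean <- screen_outliers(camp$records)
  daily <- aggregate_series(clean, "day")
  pairs <- daily |>
    tidyr::pivot_wider(id_cols = "bin_start", names_from = "position",
                       values_from = "mean") |>
    dplyr::filter(!is.na(.data$below_canopy), !is.na(.data$open_field))
  pairs <- select_season(pairs, season)
  f <- fit_line_ols(pairs$open_field, pairs$below_canopy)
  # month-aware sampling se of the OLS slope (see Details); on degenerate
  # (noise-free) data the REML fit can fail, where the iid se (zero) is exact
  mf <- factor(month_key(pairs$bin_start))
  se_beta <- tryCatch({
    lf <- suppressMessages(lme4::lmer(
      y ~ x + (1 | mf),
      data = data.frame(y = pairs$below_canopy, x = pairs$open_field, mf = mf),
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    vc <- as.data.frame(lme4::VarCorr(lf))
    s2m <- vc$vcov[vc$grp == "mf"]
    s2r <- vc$vcov[vc$grp == "Residual"]
    dev <- pairs$open_field - mean(pairs$open_field)
    a_m <- tapply(dev, mf, sum) / sum(dev^2)
    sqrt(s2r / sum(dev^2) + s2m * sum(a_m^2))
  }, error = function(e) f$se_beta)
  tibble::tibble(alpha = f$alpha, beta = f$beta,
                 se_alpha = f$se_alpha, se_beta = se_beta, n = f$n)
}
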