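# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct normal-equations algebra, trapezoid
# quadrature, and balanced-ANOVA method-of-moments estimators.

# OLS intercept/slope by a direct 2x2 normal-equations solve.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Trapezoid integration of the positive/negative parts of
# g(x) = alpha + (beta - 1) x over [x_min, x_max].
trapezoid_buffering <- function(alpha, beta, x_min, x_max, dx = 1e-4) {
  n <- max(3, ceiling((x_max - x_min) / dx) + 1)
  x <- seq(x_min, x_max, length.out = n)
  g <- alpha + (beta - 1) * x
  h <- diff(x)[1]
  trapz <- function(v) sum((v[-1] + v[-length(v)]) / 2) * h
  list(b_warm = trapz(pmax(g, 0)), b_cool = trapz(pmax(-g, 0)))
}

# Balanced three-level nested ANOVA method-of-moments variance components:
# a months x b days x c hours x r replicates.
nested_anova_oracle <- function(y, a, b, c, r) {
  stopifnot(length(y) == a * b * c * r)
  arr <- array(y, dim = c(r, c, b, a))  # replicate fastest
  m_hour <- apply(arr, c(2, 3, 4), mean)
  m_day <- apply(arr, c(3, 4), mean)
  m_month <- apply(arr, 4, mean)
  gm <- mean(y)
  ss_e <- sum((arr - array(rep(m_hour, each = r), dim(arr)))^2)
  ss_c <- r * sum((m_hour - array(rep(m_day, each = c), dim(m_hour)))^2)
  ss_b <- r * c * sum((m_day - matrix(rep(m_month, each = b), b, a))^2)
  ss_a <- r * c * b * sum((m_month - gm)^2)
  ms_e <- ss_e / (a * b * c * (r - 1))
  ms_c <- ss_c / (a * b * (c - 1))
  ms_b <- ss_b / (a * (b - 1))
  ms_a <- ss_a / (a - 1)
  list(
    mu = gm,
    sigma2_resid = ms_e,
    sigma2_hour = (ms_c - ms_e) / r,
    sigma2_day = (ms_b - ms_c) / (r * c),
    sigma2_month = (ms_a - ms_b) / (r * c * b)
  )
}

# Quiet single-site configuration used when a test needs a fast,
# deterministic campaign without injected artefacts.
quiet_site <- function(site_id = "S", ...) {
  site_config(site_id,
    ar1_sd = 0, synoptic_sd = 0,
    offset_random_sd_month = 0, offset_random_sd_day = 0,
    offset_random_sd_hour = 0,
    gap_fraction = 0, outlier_fraction = 0, ...
  )
}

year_config <- function(site, seed = 1, end = "2017-04-30", ...) {
  synth_config(list(site), start = "2016-05-01", end = end, seed = seed, ...)
}

split_positions <- function(clean, which_site = NULL, var = "air_T") {
  if (!is.null(which_site)) clean <- dplyr::filter(clean, site == which_site)
  clean <- dplyr::filter(clean, variable == var)
  list(
    below = dplyr::filter(clean, position == "below_canopy"),
    open = dplyr::filter(clean, position == "open_field")
  )
}
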