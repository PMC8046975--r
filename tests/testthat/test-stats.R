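test_that("OLS matches the normal-equations closed form and fits exact lines", {
  f <- fit_line_ols(c(0, 1, 2), c(1, 2, 3))
  expect_equal(f$alpha, 1, tolerance = 1e-12)
  expect_equal(f$beta, 1, tolerance = 1e-12)
  expect_equal(f$sigma, 0, tolerance = 1e-10)

  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(40); y <- 1.5 - 0.3 * x + rnorm(40)
    f <- fit_line_ols(x, y)
    o <- ols_oracle(x, y)
    expect_equal(c(f$alpha, f$beta), o, tolerance = 1e-12)
    # algebraic identity: slope of (y - x) on x = slope(y on x) - 1
    fd <- fit_line_ols(x, y - x)
    expect_equal(fd$beta, f$beta - 1, tolerance = 1e-12)
    expect_equal(fd$alpha, f$alpha, tolerance = 1e-12)
  }
  expect_error(fit_line_ols(rep(1, 5), 1:5), "var")
  expect_error(fit_line_ols(1:2, 1:2), "3")
})

test_that("nested intercept model reduces correctly on degenerate input", {
  v <- rep(3.2, 40)
  m <- rep(1:2, each = 20); d <- rep(1:4, each = 10); h <- rep(1:20, each = 2)
  fit <- fit_nested_intercept_model(v, m, d, h)
  expect_equal(fit$mu, 3.2)
  expect_equal(fit$se_mu, 0)
  expect_true(all(fit$sigma2 == 0))
  # same day label under two months must be rejected
  expect_error(
    fit_nested_intercept_model(rnorm(8), rep(1:2, each = 4), rep(1:2, 4)),
    "nested"
  )
})

test_that("REML variance components match the balanced-ANOVA moment oracle", {
  a <- 4; b <- 3; cc <- 4; r <- 4
  sig <- c(month = 4, day = 1, hour = 0.25, resid = 1)
  set.seed(20)
  month <- rep(seq_len(a), each = b * cc * r)
  day <- rep(rep(seq_len(a * b), each = cc * r))
  hour <- rep(rep(seq_len(a * b * cc), each = r))
  y <- 5 +
    rep(rnorm(a, 0, sqrt(sig["month"])), each = b * cc * r) +
    rep(rnorm(a * b, 0, sqrt(sig["day"])), each = cc * r) +
    rep(rnorm(a * b * cc, 0, sqrt(sig["hour"])), each = r) +
    rnorm(a * b * cc * r, 0, sqrt(sig["resid"]))
  oracle <- nested_anova_oracle(y, a, b, cc, r)
  # oracle estimates must be interior for REML equality
  expect_true(all(unlist(oracle[-1]) > 0))
  fit <- fit_nested_intercept_model(y, month, day, hour %% cc)
  expect_equal(fit$mu, oracle$mu, tolerance = 1e-6)
  rel <- function(est, truth) abs(est - truth) / max(abs(truth), 1e-8)
  expect_lt(rel(fit$sigma2[["month"]], oracle$sigma2_month), 1e-4)
  expect_lt(rel(fit$sigma2[["day"]], oracle$sigma2_day), 1e-4)
  expect_lt(rel(fit$sigma2[["hour"]], oracle$sigma2_hour), 1e-4)
  expect_lt(rel(fit$sigma2[["resid"]], oracle$sigma2_resid), 1e-4)
})

test_that("harmonic mixed line reduces to OLS without random effects and recovers truth", {
  set.seed(31)
  n <- 600
  hour <- rep(0:23, length.out = n)
  x <- rnorm(n, 15, 5)
  month <- rep(1:3, each = n / 3)
  day <- rep(1:60, each = 10)
  e <- rnorm(n, 0, 0.8)
  # remove all between-group variation so the REML variance estimates sit
  # exactly at the zero boundary (truly zero random-effect variance)
  e <- e - stats::ave(e, day)
  e <- e - stats::ave(e, month)
  y <- 5.6 - 0.51 * x + e
  fit <- fit_mixed_line(y, x, hour, month, day)
  expect_lt(abs(fit$beta[["beta0"]] - 5.6), 2 * fit$se[["beta0"]] + 0.05)
  expect_lt(abs(fit$beta[["beta1"]] + 0.51), 2 * fit$se[["beta1"]] + 0.01)
  # zero random-effect variance: estimates equal OLS on the same design
  X <- cbind(1, x, sin(2 * pi * hour / 24), cos(2 * pi * hour / 24))
  ols <- as.numeric(solve(t(X) %*% X, t(X) %*% y))
  expect_equal(unname(fit$beta), ols, tolerance = 1e-6)
  expect_error(fit_mixed_line(y, rep(1, n), hour, month, day), "var|rank")
})

test_that("slope confidence interval covers zero when y is independent of x", {
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 240
    hour <- rep(0:23, each = 10)
    month <- rep(1:3, each = 80)
    day <- rep(1:24, each = 10)
    x <- rnorm(n)
    y <- rnorm(n) + rep(rnorm(24, 0, 0.5), each = 10)
    fit <- fit_mixed_line(y, x, hour, month, day)
    ci <- fit$beta[["beta1"]] + c(-2, 2) * fit$se[["beta1"]]
    hits <- hits + (ci[1] <= 0 && 0 <= ci[2])
  }
  expect_gte(hits, 18)
})

test_that("marginal and conditional R2 behave at the edges and recover known shares", {
  set.seed(77)
  n <- 3000
  month <- rep(1:10, each = n / 10)
  day <- rep(1:300, each = 10)
  hour <- rep(0:23, length.out = n)
  # fixed variance 2, random (day) variance 1, residual 1
  x <- rnorm(n, 0, 1)
  y <- sqrt(2) * x + rep(rnorm(300, 0, 1), each = 10) + rnorm(n, 0, 1)
  fit <- fit_mixed_line(y, x, hour, month, day)
  expect_true(fit$r2m <= fit$r2c)
  expect_true(fit$r2c <= 1)
  expect_equal(fit$r2m, 0.5, tolerance = 0.05)
  expect_equal(fit$r2c, 0.75, tolerance = 0.05)
  # no fixed effect: R2m near zero
  y0 <- rep(rnorm(300), each = 10) + rnorm(n)
  fit0 <- fit_mixed_line(y0, x, hour, month, day)
  expect_lt(fit0$r2m, 0.01)
})

test_that("penalized spline finds the linear limit and smooth curvature", {
  set.seed(5)
  x <- runif(200, -2, 2)
  y_lin <- 2 + 0.5 * x + rnorm(200, 0, 0.05)
  sf <- fit_penalized_spline(y_lin, x)
  expect_lte(sf$edf, 1.2)
  ols <- ols_oracle(x, y_lin)
  line_on_grid <- ols[1] + ols[2] * sf$curve$x
  expect_lt(max(abs(sf$curve$fit - line_on_grid)), 0.05)

  y_quad <- x^2 + rnorm(200, 0, 0.05)
  sq <- fit_penalized_spline(y_quad, x)
  expect_gt(sq$edf, 2)
  expect_lt(sqrt(mean((sq$curve$fit - sq$curve$x^2)^2)), 0.1)
  expect_error(fit_penalized_spline(rnorm(10), rnorm(10)), "n >= 20")
})

test_that("likelihood-ratio comparison is exact for identical models and powerful for strong effects", {
  set.seed(12)
  d <- data.frame(x = rnorm(1000))
  d$y <- 2 - 0.5 * d$x + rnorm(1000, 0, 0.1)
  full <- lm(y ~ x, d)
  null <- lm(y ~ 1, d)
  same <- lrt_compare(full, full)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  strong <- lrt_compare(full, null)
  expect_equal(strong$df, 1)
  expect_lt(strong$p, 1e-6)
  expect_error(lrt_compare(null, full), "lower likelihood")
})

test_that("Tukey letters separate distinct groups, merge identical ones, and ignore labels", {
  set.seed(3)
  v <- c(rnorm(50, 0), rnorm(50, 0), rnorm(50, 5))
  g <- rep(c("g1", "g2", "g3"), each = 50)
  at <- anova_tukey(v, g)
  expect_equal(at$letters[["g1"]], at$letters[["g2"]])
  expect_false(at$letters[["g3"]] %in% at$letters[c("g1", "g2")])

  v0 <- rep(rnorm(30), 4) + rnorm(120, 0, 1)
  at0 <- anova_tukey(v0, rep(c("p", "q", "r", "s"), each = 30))
  expect_true(length(unique(at0$letters)) == 1)

  # relabelling permutes rows but not the p-values
  relab <- c(g1 = "zz", g2 = "aa", g3 = "mm")
  at2 <- anova_tukey(v, relab[g])
  expect_equal(sort(at$tukey$p_adj), sort(at2$tukey$p_adj), tolerance = 1e-12)
  expect_error(anova_tukey(c(1, 2), c("a", "b")), "2 observations")
})

test_that("groups calibrated to the observed open/canopy contrast separate at n = 153 days", {
  # daily growing-season means: open field 15.3 degC vs below canopy 13.1 degC
  set.seed(41)
  open <- rnorm(153, 15.3, 3.5)
  canopy <- rnorm(153, 13.1, 3.0)
  at <- anova_tukey(c(open, canopy),
                    rep(c("S_open", "S_canopy"), each = 153))
  expect_lt(at$p, 0.001)
  expect_false(at$letters[["S_open"]] == at$letters[["S_canopy"]])
})
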