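#' Ordinary least-squares line fit
#'
#' Simple linear regression `y ~ x` with exact closed-form standard errors;
#' pairs with a missing member are dropped listwise.
#'
#' @param x,y Numeric vectors of equal length.
#' @return An object of class `line_fit`: intercept `alpha`, slope `beta`,
#'   their standard errors, `sigma` (residual sd), `n`, and `cov_ab`.
#' @export
fit_line_ols <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (var(x) == 0) stop("var(x) is zero", call. = FALSE)
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(
    list(
      alpha = unname(coef(fit)[1]), beta = unname(coef(fit)[2]),
      se_alpha = sm$coefficients[1, 2], se_beta = sm$coefficients[2, 2],
      sigma = sm$sigma, n = n, cov_ab = vcov(fit)[1, 2],
      r_squared = sm$r.squared, model = fit
    ),
    class = "line_fit"
  )
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf("OLS line: intercept %.4f (se %.4f), slope %.4f (se %.4f), n = %d\n",
              x$alpha, x$se_alpha, x$beta, x$se_beta, x$n))
  invisible(x)
}

#' Intercept-only model with nested random intercepts
#'
#' REML fit of `value ~ 1 + (1 | month) + (1 | month:day) [+ (1 |
#' month:day:hour)]`, the estimator used for seasonal temperature offsets:
#' the fixed intercept `mu` is the average offset while the nested grouping
#' absorbs the non-independence of replicates from the same month, day and
#' hour. Day labels must be nested within months (the same day label under
#' two months is an error); hour-of-day labels are composed into
#' month:day:hour cells internally, so cyclic 0-23 labels are the expected
#' input (each hour cell then holds the records of that hour).
#'
#' @param values Numeric response.
#' @param month,day Grouping labels; `day` may be `NULL` for a month-only
#'   model.
#' @param hour Optional hour labels; `NULL` drops the hour level (used for
#'   daily-resolution responses, where the day level is the residual).
#' @return An object of class `var_comp`: `mu`, `se_mu`, variance components
#'   `sigma2` (named: month, day, hour, resid; absent levels are `NA`),
#'   `loglik` (REML criterion), `n`, and the underlying `lmerMod` as `model`.
#' @export
fit_nested_intercept_model <- function(values, month, day = NULL, hour = NULL) {
  n_in <- length(values)
  stopifnot(length(month) == n_in,
            is.null(day) || length(day) == n_in,
            is.null(hour) || length(hour) == n_in)
  keep <- !is.na(values)
  values <- values[keep]
  month <- as.character(month)[keep]
  if (!is.null(day)) day <- as.character(day)[keep]
  if (!is.null(hour)) hour <- as.character(hour)[keep]
  n <- length(values)
  if (n < 3) stop("too few observations", call. = FALSE)
  if (!is.null(day)) {
    tab <- unique(data.frame(month, day))
    if (anyDuplicated(tab$day)) {
      stop("day labels are not nested within months", call. = FALSE)
    }
  }
  if (var(values) == 0) {
    sig <- c(month = 0, day = if (is.null(day)) NA_real_ else 0,
             hour = if (is.null(hour)) NA_real_ else 0, resid = 0)
    return(structure(list(mu = values[1], se_mu = 0, sigma2 = sig,
                          loglik = NA_real_, n = n, model = NULL),
                     class = "var_comp"))
  }
  dat <- data.frame(value = values, mf = factor(month))
  terms <- "(1 | mf)"
  if (!is.null(day)) {
    dat$df <- factor(paste(month, day, sep = ":"))
    terms <- c(terms, "(1 | df)")
  }
  if (!is.null(hour)) {
    if (is.null(day)) stop("hour grouping requires day labels", call. = FALSE)
    dat$hf <- factor(paste(month, day, hour, sep = ":"))
    terms <- c(terms, "(1 | hf)")
  }
  form <- stats::as.formula(paste("value ~ 1 +", paste(terms, collapse = " + ")))
  # tight optimizer tolerances: balanced designs must reproduce the
  # closed-form ANOVA estimators to ~1e-4 relative
  fit <- suppressMessages(lme4::lmer(form, data = dat, REML = TRUE,
    control = lme4::lmerControl(
      check.conv.singular = "ignore",
      optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-12))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_var <- function(g) {
    i <- match(g, vc$grp)
    if (is.na(i)) NA_real_ else vc$vcov[i]
  }
  structure(
    list(
      mu = unname(lme4::fixef(fit)[1]),
      se_mu = sqrt(vcov(fit)[1, 1]),
      sigma2 = c(month = get_var("mf"),
                 day = if (is.null(day)) NA_real_ else get_var("df"),
                 hour = if (is.null(hour)) NA_real_ else get_var("hf"),
                 resid = get_var("Residual")),
      loglik = as.numeric(logLik(fit)),
      n = n, model = fit
    ),
    class = "var_comp"
  )
}

#' @export
print.var_comp <- function(x, ...) {
  cat(sprintf("Nested random-intercept model: mu = %.4f (se %.4f), n = %d\n",
              x$mu, x$se_mu, x$n))
  cat("variance components (sigma^2):\n")
  print(round(x$sigma2, 5))
  invisible(x)
}

#' Mixed-effects line with diurnal harmonics
#'
#' REML fit of `y ~ x + sin(2*pi*h/24) + cos(2*pi*h/24) + (1 | month) +
#' (1 | month:day)`: the offset- or temperature-response model with the
#' open-field temperature and daytime harmonics as fixed effects and nested
#' month/day random intercepts.
#'
#' @param y,x Numeric response and predictor.
#' @param hour Hour of day (0-23, fractional allowed) for the harmonics.
#' @param month,day Nesting labels (day nested in month).
#' @return An object of class `mixed_line_fit`: coefficients `beta0..beta3`
#'   with standard errors, random-effect variances, `loglik`, Nakagawa
#'   `r2m`/`r2c`, and the `lmerMod` as `model`.
#' @export
fit_mixed_line <- function(y, x, hour, month, day) {
  keep <- complete.cases(y, x)
  dat <- data.frame(
    y = y[keep], x = x[keep],
    s = sin(2 * pi * hour[keep] / 24), c = cos(2 * pi * hour[keep] / 24),
    mf = factor(as.character(month)[keep])
  )
  dat$df <- factor(paste(as.character(month)[keep], as.character(day)[keep],
                         sep = ":"))
  if (var(dat$x) == 0) stop("var(x) is zero", call. = FALSE)
  X <- cbind(1, dat$x, dat$s, dat$c)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient fixed-effect design", call. = FALSE)
  fit <- suppressMessages(lme4::lmer(
    y ~ x + s + c + (1 | mf) + (1 | df), data = dat, REML = TRUE,
    control = lme4::lmerControl(
      check.conv.singular = "ignore",
      optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-12))))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  r2 <- r2_mixed_lmer(fit)
  structure(
    list(
      beta = setNames(unname(beta), c("beta0", "beta1", "beta2", "beta3")),
      se = setNames(unname(se), c("beta0", "beta1", "beta2", "beta3")),
      sigma2 = setNames(vc$vcov, vc$grp),
      loglik = as.numeric(logLik(fit)),
      r2m = r2$r2m, r2c = r2$r2c,
      n = nrow(dat), model = fit
    ),
    class = "mixed_line_fit"
  )
}

#' @export
print.mixed_line_fit <- function(x, ...) {
  cat(sprintf(
    "Harmonic mixed line: intercept %.3f, slope %.3f (se %.3f), R2m %.3f, R2c %.3f\n",
    x$beta[1], x$beta[2], x$se[2], x$r2m, x$r2c))
  invisible(x)
}

#' Marginal and conditional R-squared of a mixed line fit
#'
#' Nakagawa decomposition: `R2m` is the variance of the fixed-effect
#' predictions over the total (fixed + random intercepts + residual)
#' variance; `R2c` additionally credits the random intercepts.
#'
#' @param fit A [fit_mixed_line()] result (or an `lmerMod`).
#' @return List with `r2m` and `r2c` (`r2m <= r2c <= 1`).
#' @export
r2_mixed <- function(fit) {
  if (inherits(fit, "mixed_line_fit")) fit <- fit$model
  r2_mixed_lmer(fit)
}

r2_mixed_lmer <- function(fit) {
  X <- lme4::getME(fit, "X")
  pred <- as.numeric(X %*% lme4::fixef(fit))
  var_f <- sum((pred - mean(pred))^2) / length(pred)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_r <- sum(vc$vcov[vc$grp != "Residual"])
  var_e <- vc$vcov[vc$grp == "Residual"]
  tot <- var_f + var_r + var_e
  if (tot <= 0) stop("zero total variance", call. = FALSE)
  list(r2m = var_f / tot, r2c = (var_f + var_r) / tot)
}

#' Penalized cubic spline smoother
#'
#' Cubic B-spline basis with a second-order difference penalty, smoothing
#' parameter chosen by generalized cross-validation (GCV); the nonlinearity
#' check used against the linear offset-response model. Reports the smooth's
#' effective degrees of freedom (1 = linear limit) and the fitted curve with
#' pointwise standard errors on a grid.
#'
#' @param y,x Numeric response and predictor (`n >= 20`).
#' @param k Basis dimension (default 13: about ten interior knots).
#' @param grid_n Length of the evaluation grid over the range of `x`.
#' @return An object of class `spline_fit`: `edf`, `lambda`, `knots`,
#'   `coefficients`, a tibble `curve` (`x, fit, se`), and the `gam` object.
#' @export
fit_penalized_spline <- function(y, x, k = 13, grid_n = 200) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 20) stop("need n >= 20", call. = FALSE)
  if (n <= k) stop("n must exceed the basis dimension", call. = FALSE)
  dat <- data.frame(x = x, y = y)
  fit <- mgcv::gam(y ~ s(x, bs = "ps", k = k, m = c(2, 2)), data = dat,
                   method = "GCV.Cp")
  grid <- data.frame(x = seq(min(x), max(x), length.out = grid_n))
  pr <- predict(fit, newdata = grid, se.fit = TRUE)
  structure(
    list(
      edf = sum(summary(fit)$edf),
      lambda = unname(fit$sp),
      knots = fit$smooth[[1]]$knots,
      coefficients = coef(fit),
      curve = tibble::tibble(x = grid$x, fit = as.numeric(pr$fit),
                             se = as.numeric(pr$se.fit)),
      n = n, model = fit
    ),
    class = "spline_fit"
  )
}

#' @export
print.spline_fit <- function(x, ...) {
  cat(sprintf("Penalized spline: edf %.2f, lambda %.3g, n = %d\n",
              x$edf, x$lambda, x$n))
  invisible(x)
}

#' Likelihood-ratio comparison of nested models
#'
#' Chi-squared test `2 * (ll_full - ll_null)` with degrees of freedom equal
#' to the parameter-count difference. Mixed models fitted by REML are
#' refitted with maximum likelihood internally (REML criteria are not
#' comparable across fixed-effect structures); estimates elsewhere are still
#' reported from the REML fits.
#'
#' @param fit_full,fit_null Fitted models (`lmerMod`, `lm`, `gam`, or the
#'   wrapper classes from this package).
#' @return List with `chisq`, `df`, `p`.
#' @export
lrt_compare <- function(fit_full, fit_null) {
  ll <- function(f) {
    if (inherits(f, c("var_comp", "mixed_line_fit", "line_fit", "spline_fit"))) {
      f <- f$model
    }
    if (inherits(f, "lmerMod") && lme4::isREML(f)) f <- lme4::refitML(f)
    logLik(f)
  }
  l1 <- ll(fit_full)
  l0 <- ll(fit_null)
  chisq <- 2 * (as.numeric(l1) - as.numeric(l0))
  if (chisq < -1e-6) {
    stop("full model has lower likelihood than null: non-nested or non-converged",
         call. = FALSE)
  }
  chisq <- max(chisq, 0)
  df <- attr(l1, "df") - attr(l0, "df")
  p <- if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else 1
  list(chisq = chisq, df = df, p = p)
}

#' One-way ANOVA with Tukey HSD and a compact letter display
#'
#' Group comparison of daily means: one-way ANOVA F test, Tukey's honestly
#' significant difference from the studentized-range distribution (the
#' Tukey-Kramer form under unequal group sizes, as implemented by
#' [stats::TukeyHSD()]), and a compact letter display at level `alpha`
#' (groups sharing a letter are not significantly different).
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @param alpha Significance level for the letter display.
#' @return List with `f`, `p`, `tukey` (tibble of pairwise contrasts) and
#'   `letters` (named character vector, groups ordered by decreasing mean).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  g <- factor(as.character(groups)[keep])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs at least 2 observations",
                              call. = FALSE)
  fit <- aov(values ~ g)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  contrasts <- rownames(tk)
  pairs <- do.call(rbind, strsplit(contrasts, "-", fixed = TRUE))
  tukey <- tibble::tibble(
    group1 = pairs[, 1], group2 = pairs[, 2],
    diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]), p_adj = unname(tk[, "p adj"])
  )
  means <- sort(tapply(values, g, mean), decreasing = TRUE)
  letters <- letter_display(names(means), tukey, alpha)
  list(
    f = an[["F value"]][1], p = an[["Pr(>F)"]][1],
    tukey = tukey, letters = letters, model = fit
  )
}

# Insert-and-absorb compact letter display from a pairwise p-value table.
letter_display <- function(ordered_groups, tukey, alpha) {
  sets <- list(ordered_groups)
  sig <- tukey[tukey$p_adj < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$group1[i]; b <- sig$group2[i]
    new_sets <- list()
    for (s in sets) {
      if (all(c(a, b) %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    sets <- absorb_sets(new_sets)
  }
  sets <- sets[lengths(sets) > 0]
  # order sets by the position of their first group, assign letters
  first_pos <- vapply(sets, function(s) min(match(s, ordered_groups)), 1)
  sets <- sets[order(first_pos)]
  out <- setNames(rep("", length(ordered_groups)), ordered_groups)
  for (i in seq_along(sets)) {
    for (gname in sets[[i]]) out[gname] <- paste0(out[gname], letters[i])
  }
  out
}

# Deduplicate and drop sets strictly contained in another set.
absorb_sets <- function(sets) {
  sets <- unique(lapply(sets, sort))
  keep <- rep(TRUE, length(sets))
  for (j in seq_along(sets)) {
    for (l in seq_along(sets)) {
      if (j != l && keep[l] && length(sets[[j]]) < length(sets[[l]]) &&
          all(sets[[j]] %in% sets[[l]])) {
        keep[j] <- FALSE
      }
    }
  }
  sets[keep]
}
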