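#' @importFrom rlang .data
#' @importFrom stats var sd coef vcov logLik pchisq qt pt lm aov TukeyHSD
#'   predict rnorm runif rbinom quantile median loess approx uniroot setNames
#'   complete.cases
#' @importFrom utils head tail
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stationary AR(1) path: marginal sd `sd`, lag-one correlation `rho`.
ar1_series <- function(n, rho, sd) {
  if (sd <= 0 || n == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - rho^2)
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd)
  if (n > 1) {
    z <- rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) e[i] <- rho * e[i - 1] + z[i - 1]
  }
  e
}

# Column-wise stationary AR(1) paths for an n x m matrix (vectorised over m).
ar1_matrix <- function(n, m, rho, sd) {
  e <- matrix(0, n, m)
  if (sd <= 0) return(e)
  innov_sd <- sd * sqrt(1 - rho^2)
  e[1, ] <- rnorm(m, 0, sd)
  if (n > 1) {
    for (i in 2:n) e[i, ] <- rho * e[i - 1, ] + rnorm(m, 0, innov_sd)
  }
  e
}

# Month key used for nested random-intercept grouping, e.g. "2016-05".
month_key <- function(x) format(x, "%Y-%m")

# Season month sets. GS = May 1 - Sep 30; DJF spans the year boundary.
season_months <- function(season) {
  switch(season,
    JJA = 6:8,
    DJF = c(12L, 1L, 2L),
    GS  = 5:9,
    stop("unknown season: ", season, call. = FALSE)
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
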