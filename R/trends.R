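#' Elevational trend by AIC-selected polynomial regression
#'
#' Fits ordinary least-squares regressions of a (possibly transformed)
#' metric on elevation, degree 1 and degree 2, and keeps the model with the
#' lower AIC, computed as \eqn{n \ln(RSS/n) + 2k} with \eqn{k} = degree + 2
#' (intercept, slope coefficients, and the error variance; additive
#' constants cancel in the comparison). The F statistic, \eqn{r^2} and
#' p-value of the selected model come from standard OLS theory. Pairs where
#' the metric is undefined are dropped and `n` reports the pairs actually
#' used.
#'
#' @param x Elevations (m a.s.l.).
#' @param y Metric values (may contain `NA`).
#' @param transformation One of `"none"`, `"sqrt"`, `"log"` applied to `y`
#'   before fitting (`"log"` requires all y > 0).
#' @param max_degree Highest polynomial degree considered (default 2).
#' @param metric Optional metric name carried into the result.
#' @return A one-row data frame: `metric`, `method` (`"regression"`),
#'   `transformation`, `degree`, `statistic` (F), `r_squared`, `p_value`,
#'   `n`. All-`NA` statistics if fewer than `degree + 2` usable pairs exist
#'   for even the linear model.
#' @examples
#' fit_trend(1:8, (1:8) * 2 + 1)           # exact line: degree 1, r2 = 1
#' fit_trend(1:8, (1:8 - 4)^2)             # curvature: degree 2 selected
#' @export
fit_trend <- function(x, y, transformation = c("none", "sqrt", "log"),
                      max_degree = 2L, metric = NA_character_) {
  transformation <- match.arg(transformation)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  empty <- data.frame(
    metric = metric, method = "regression", transformation = transformation,
    degree = NA_integer_, statistic = NA_real_, r_squared = NA_real_,
    p_value = NA_real_, n = n
  )
  if (n < 3L) return(empty)
  ty <- switch(transformation,
    none = y,
    sqrt = {
      if (any(y < 0)) stop("sqrt transformation requires non-negative values")
      sqrt(y)
    },
    log = {
      if (any(y <= 0)) {
        stop("log transformation requires positive values; offending x = ",
             paste(x[y <= 0], collapse = ", "))
      }
      log(y)
    }
  )
  fits <- list()
  for (deg in seq_len(max_degree)) {
    if (n < deg + 2L) next
    fits[[deg]] <- stats::lm(ty ~ stats::poly(x, deg, raw = TRUE))
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) return(empty)
  aics <- vapply(fits, function(f) {
    rss <- sum(stats::residuals(f)^2)
    k <- length(stats::coef(f)) + 1
    n * log(rss / n) + 2 * k
  }, numeric(1))
  best <- fits[[which.min(aics)]]
  sm <- summary(best)
  fstat <- sm$fstatistic
  data.frame(
    metric = metric, method = "regression", transformation = transformation,
    degree = length(stats::coef(best)) - 1L,
    statistic = unname(fstat[1L]),
    r_squared = sm$r.squared,
    p_value = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                               lower.tail = FALSE)),
    n = n
  )
}

#' Hoeffding's D statistic of bivariate dependence
#'
#' The classical rank-based D, sensitive to non-monotonic association. With
#' midranks \eqn{R_i, S_i} of x and y and bivariate ranks
#' \eqn{Q_i = 1 + \sum_{j \ne i} u(x_i - x_j)\,u(y_i - y_j)} (where
#' \eqn{u(t)} is 1, 1/2, 0 for \eqn{t} positive, zero, negative — midrank
#' tie handling throughout),
#' \deqn{D = 30\,\frac{(n-2)(n-3)D_1 + D_2 - 2(n-2)D_3}
#'           {n(n-1)(n-2)(n-3)(n-4)}}
#' with \eqn{D_1 = \sum (Q_i-1)(Q_i-2)},
#' \eqn{D_2 = \sum (R_i-1)(R_i-2)(S_i-1)(S_i-2)},
#' \eqn{D_3 = \sum (R_i-2)(S_i-2)(Q_i-1)}.
#'
#' @param x,y Numeric vectors of equal length, n >= 5.
#' @return The D statistic. A constant x or y gives 0, flagged with
#'   attribute `degenerate = TRUE`.
#' @examples
#' hoeffding_d(1:10, (1:10)^2)   # monotone: maximal for this n
#' @export
hoeffding_d <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 5L) stop("Hoeffding's D requires n >= 5")
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(structure(0, degenerate = TRUE))
  }
  r <- rank(x)
  s <- rank(y)
  u <- function(t) (sign(t) + 1) / 2
  q <- vapply(seq_len(n), function(i) {
    1 + sum(u(x[i] - x[-i]) * u(y[i] - y[-i]))
  }, numeric(1))
  d1 <- sum((q - 1) * (q - 2))
  d2 <- sum((r - 1) * (r - 2) * (s - 1) * (s - 2))
  d3 <- sum((r - 2) * (s - 2) * (q - 1))
  30 * ((n - 2) * (n - 3) * d1 + d2 - 2 * (n - 2) * d3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

#' Permutation test of dependence based on Hoeffding's D
#'
#' Permutes y, recomputes D, and reports the add-one one-tailed p-value on
#' large D (dependence of any shape inflates D). The asymptotic null table
#' is not used: the permutation null is exact-in-distribution, self-
#' contained and reproducible under seed.
#'
#' @param x,y Numeric vectors (undefined pairs dropped first).
#' @param n_perm Number of permutations (default 10000).
#' @param metric Optional metric name carried into the result.
#' @return A one-row data frame: `metric`, `method` (`"hoeffding"`),
#'   `transformation` (`"none"`), `degree` (`NA`), `statistic` (D),
#'   `r_squared` (`NA`), `p_value`, `n`.
#' @export
hoeffding_test <- function(x, y, n_perm = 10000L, metric = NA_character_) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 5L) {
    return(data.frame(
      metric = metric, method = "hoeffding", transformation = "none",
      degree = NA_integer_, statistic = NA_real_, r_squared = NA_real_,
      p_value = NA_real_, n = n
    ))
  }
  d_obs <- hoeffding_d(x, y)
  d_null <- vapply(seq_len(n_perm), function(i) {
    hoeffding_d(x, sample(y))
  }, numeric(1))
  p <- (1 + sum(d_null >= d_obs - 1e-12)) / (n_perm + 1)
  data.frame(
    metric = metric, method = "hoeffding", transformation = "none",
    degree = NA_integer_, statistic = as.numeric(d_obs), r_squared = NA_real_,
    p_value = p, n = n
  )
}
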