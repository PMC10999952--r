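#' Second-order polynomial trend regression between annual series
#'
#' Ordinary least squares of an annual index on a centered annual
#' covariate and its square, `y = b0 + b1 (x - xbar) + b2 (x - xbar)^2`,
#' with t-test p-values at `alpha = 0.05`.  When the quadratic term is not
#' significant a linear-only submodel is also reported.  For significant
#' quadratic fits the vertex (the covariate value at the curve extremum,
#' `xbar - b1 / (2 b2)`) is returned on the raw covariate scale.
#'
#' @param x Annual covariate values (>= 4 finite pairs required).
#' @param y Annual index values.
#' @param alpha Significance level (default 0.05).
#' @return A `trend_fit` list: `coefficients` (b0, b1, b2), `se`,
#'   `p_values`, `r_squared`, `vertex` (NA unless b2 significant),
#'   `quadratic_significant`, `linear` (submodel when b2 not significant),
#'   `n`.
#' @export
fit_trend <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 paired finite years")
  if (var(x) == 0) stop("covariate has zero variance")
  xbar <- mean(x)
  xc <- x - xbar
  m <- lm(y ~ xc + I(xc^2))
  sm <- summary(m)
  co <- sm$coefficients
  b <- setNames(co[, "Estimate"], c("b0", "b1", "b2"))
  p <- setNames(co[, "Pr(>|t|)"], c("b0", "b1", "b2"))
  quad_sig <- p["b2"] < alpha
  vertex <- if (quad_sig) unname(xbar - b["b1"] / (2 * b["b2"])) else
    NA_real_
  linear <- NULL
  if (!quad_sig) {
    ml <- summary(lm(y ~ xc))
    linear <- list(
      coefficients = setNames(ml$coefficients[, "Estimate"],
                              c("b0", "b1")),
      p_values = setNames(ml$coefficients[, "Pr(>|t|)"], c("b0", "b1")),
      r_squared = ml$r.squared)
  }
  structure(list(coefficients = b,
                 se = setNames(co[, "Std. Error"], c("b0", "b1", "b2")),
                 p_values = p, r_squared = sm$r.squared,
                 vertex = vertex,
                 quadratic_significant = unname(quad_sig),
                 linear = linear, alpha = alpha, x_center = xbar,
                 n = length(x)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  b <- x$coefficients; p <- x$p_values
  cat(sprintf("trend_fit (n = %d): y = %.4g %+.4g (x - %.4g) %+.4g (x - %.4g)^2\n",
              x$n, b["b0"], b["b1"], x$x_center, b["b2"], x$x_center))
  cat(sprintf("  p(b1) = %.3g, p(b2) = %.3g, R2 = %.3f\n",
              p["b1"], p["b2"], x$r_squared))
  if (x$quadratic_significant) {
    cat(sprintf("  quadratic significant; vertex at x = %.4g\n",
                x$vertex))
  } else if (!is.null(x$linear)) {
    cat(sprintf("  quadratic not significant; linear slope %.4g (p = %.3g)\n",
                x$linear$coefficients["b1"], x$linear$p_values["b1"]))
  }
  invisible(x)
}

#' Trend regressions between all pairs of annual series
#'
#' Fits [fit_trend()] for each response/predictor pair and collates the
#' coefficients, p-values, and vertices into one table.  No
#' multiple-testing correction is applied; the number of tests run is
#' recorded in the `n_tests` attribute.
#'
#' @param series data.frame with a `year` column and one column per
#'   annual series.
#' @param responses,predictors Column names; every response is regressed
#'   on every predictor (skipping self-pairs).
#' @return data.frame of one row per pair.
#' @export
trend_table <- function(series, responses, predictors) {
  rows <- list()
  for (rv in responses) for (pv in predictors) {
    if (rv == pv) next
    tf <- fit_trend(series[[pv]], series[[rv]])
    rows[[length(rows) + 1L]] <- data.frame(
      response = rv, predictor = pv,
      b0 = tf$coefficients["b0"], b1 = tf$coefficients["b1"],
      b2 = tf$coefficients["b2"],
      p_b1 = tf$p_values["b1"], p_b2 = tf$p_values["b2"],
      r_squared = tf$r_squared, vertex = tf$vertex,
      quadratic_significant = tf$quadratic_significant,
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_tests") <- nrow(out)
  out
}
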