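#' Field variance parameters
#'
#' Marginal standard deviations of the two spatial fields (`omega1`,
#' `omega2`, time-invariant) and the two spatio-temporal fields (`eps1`,
#' `eps2`, independent across years), plus the shared decorrelation range:
#' the distance at which the Matern (nu = 1) correlation falls to 0.1.
#'
#' @param sd_omega1,sd_omega2,sd_eps1,sd_eps2 Marginal SDs (log-density
#'   units), all `>= 0`.
#' @param range_km Decorrelation range in km, `> 0`.
#' @return A `field_params` list.
#' @export
field_params <- function(sd_omega1 = 0.7, sd_omega2 = 0.4,
                         sd_eps1 = 0.5, sd_eps2 = 0.3, range_km = 150) {
  sds <- c(sd_omega1, sd_omega2, sd_eps1, sd_eps2)
  if (any(sds < 0)) stop("field SDs must be >= 0")
  if (range_km <= 0) stop("range_km must be > 0")
  structure(list(sd_omega1 = sd_omega1, sd_omega2 = sd_omega2,
                 sd_eps1 = sd_eps1, sd_eps2 = sd_eps2,
                 range_km = range_km),
            class = "field_params")
}

# Scale constant x* solving x K_1(x) = 0.1, so that kappa = x*/range gives
# correlation 0.1 at the stated range.  Memoised after first use.
matern_kappa_scale <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- uniroot(function(x) x * besselK(x, 1) - 0.1,
                      c(0.1, 10), tol = 1e-12)$root
    }
    val
  }
})

#' Matern (nu = 1) correlation matrix
#'
#' `C(d) = (kappa d) K_1(kappa d)` with `kappa` chosen so that the
#' correlation equals 0.1 at `range_km`; `C(0) = 1`.  A jitter of 1e-8 is
#' added to the diagonal to keep the matrix numerically positive definite.
#'
#' @param dist_matrix Symmetric matrix of distances (km) with zero diagonal.
#' @param range_km Distance at which correlation = 0.1.
#' @return Correlation matrix of the same dimension.
#' @export
matern_correlation <- function(dist_matrix, range_km) {
  dist_matrix <- as.matrix(dist_matrix)
  if (!isSymmetric(unname(dist_matrix), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  if (any(dist_matrix < 0)) stop("distances must be >= 0")
  if (range_km <= 0) stop("range_km must be > 0")
  kd <- (matern_kappa_scale() / range_km) * dist_matrix
  C <- ifelse(kd > 0, kd * besselK(kd, 1), 1)
  diag(C) <- 1 + 1e-8
  C
}

#' Simulate spatial and spatio-temporal Gaussian random fields at knots
#'
#' `omega` fields are a single mean-zero multivariate-normal draw over
#' knots; `eps` fields are drawn independently for each year.  All four
#' share one Matern correlation; each has its own marginal SD.
#'
#' @param mesh A [build_mesh()] `survey_mesh`.
#' @param params A [field_params()] object.
#' @param n_years Number of years for the `eps` fields.
#' @param seed Integer seed.
#' @return A `field_realization` list: `omega1`, `omega2` (length
#'   `n_knots`), `eps1`, `eps2` (`n_knots x n_years`).
#' @export
simulate_fields <- function(mesh, params, n_years, seed) {
  C <- matern_correlation(mesh$distances, params$range_km)
  L <- t(chol(C))     # lower triangular, C = L L'
  n <- nrow(C)
  with_seed(seed, {
    draw <- function(sd_val, m) {
      if (sd_val == 0) return(matrix(0, n, m))
      matrix(sd_val * (L %*% matrix(rnorm(n * m), n, m)), n, m)
    }
    structure(list(
      omega1 = drop(draw(params$sd_omega1, 1)),
      omega2 = drop(draw(params$sd_omega2, 1)),
      eps1 = draw(params$sd_eps1, n_years),
      eps2 = draw(params$sd_eps2, n_years)
    ), class = "field_realization")
  })
}

#' Exact Gaussian log-density of a field realization
#'
#' Evaluates the multivariate-normal log-density of each component under
#' its `sd^2 * C` covariance (Cholesky-based); years of the `eps` fields
#' contribute independently.  Components with `sd = 0` must be all-zero and
#' contribute 0.
#'
#' @param values A `field_realization` (or any list with the same names).
#' @param params A [field_params()] object.
#' @param mesh The `survey_mesh` the fields live on.
#' @return Total log-density (scalar).
#' @export
field_log_density <- function(values, params, mesh) {
  C <- matern_correlation(mesh$distances, params$range_km)
  L <- chol(C)
  ldetC <- 2 * sum(log(diag(L)))
  n <- nrow(C)
  comp <- function(x, sd_val) {
    x <- as.matrix(x)
    if (sd_val == 0) {
      if (any(x != 0)) stop("non-zero field with sd = 0 has density zero")
      return(0)
    }
    m <- ncol(x)
    q <- sum(backsolve(L, x, transpose = TRUE)^2) / sd_val^2
    -0.5 * (m * n * log(2 * pi) + m * (ldetC + 2 * n * log(sd_val)) + q)
  }
  comp(values$omega1, params$sd_omega1) +
    comp(values$omega2, params$sd_omega2) +
    comp(values$eps1, params$sd_eps1) +
    comp(values$eps2, params$sd_eps2)
}

#' Project knot-level field values to stations
#'
#' Stations inherit the value at their nearest knot (piecewise-constant
#' projection).
#'
#' @param values Vector (per knot) or matrix (knot x year).
#' @param mesh The `survey_mesh`.
#' @param year Optional year index per station for matrix-valued fields.
#' @return Per-station values.
#' @export
project_to_stations <- function(values, mesh, year = NULL) {
  s <- mesh$station_to_knot
  if (is.matrix(values)) {
    if (is.null(year)) stop("year index required for knot x year fields")
    values[cbind(s, year)]
  } else {
    values[s]
  }
}
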