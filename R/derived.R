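#' Predict the density surface over the extrapolation grid
#'
#' For each grid cell and year, assembles the linear predictors from the
#' year intercepts, the nearest-knot random-effect modes, and (when the
#' model has a covariate) the covariate effect, then evaluates the density
#' `d = r1 * r2` at unit effort, i.e. density per unit area swept.  Cells
#' whose covariate value is missing are emitted as `NA` and excluded from
#' downstream indices with a logged count.
#'
#' @param fit A `delta_fit`.
#' @param years Years to predict (default: all fitted years).
#' @param grid_covariates For covariate models, a data.frame with columns
#'   `cell_id`, `year`, `value` giving the covariate on the grid.
#' @return A `density_surface` data.frame: `cell_id, x_km, y_km, area_km2,
#'   year, density`.
#' @export
predict_density <- function(fit, years = NULL, grid_covariates = NULL) {
  if (is.null(years)) years <- fit$years
  g <- fit$mesh$grid
  inc <- fit$config$fields
  out <- vector("list", length(years))
  n_missing <- 0L
  for (j in seq_along(years)) {
    yr <- years[j]
    yi <- match(yr, fit$years)
    if (is.na(yi)) stop("year ", yr, " not in fit")
    p1 <- rep(fit$alpha1[yi], nrow(g))
    p2 <- rep(fit$alpha2[yi], nrow(g))
    k <- g$knot_id
    if (inc[1]) p1 <- p1 + fit$re_modes$omega1[k]
    if (inc[3]) p1 <- p1 + fit$re_modes$eps1[cbind(k, yi)]
    if (inc[2]) p2 <- p2 + fit$re_modes$omega2[k]
    if (inc[4]) p2 <- p2 + fit$re_modes$eps2[cbind(k, yi)]
    if (!is.null(fit$basis)) {
      if (is.null(grid_covariates)) {
        stop("model has covariate '", fit$basis$name,
             "'; supply grid_covariates (cell_id, year, value)")
      }
      gc <- grid_covariates[grid_covariates$year == yr, , drop = FALSE]
      v <- gc$value[match(g$cell_id, gc$cell_id)]
      X <- suppressWarnings(predict(fit$basis, v))
      p1 <- p1 + drop(X %*% fit$gamma1)
      if (length(fit$gamma2)) p2 <- p2 + drop(X %*% fit$gamma2)
      n_missing <- n_missing + sum(is.na(v))
    }
    lk <- poisson_link(p1, p2, rep(1, nrow(g)))
    out[[j]] <- data.frame(cell_id = g$cell_id, x_km = g$x_km,
                           y_km = g$y_km, area_km2 = g$area_km2,
                           year = yr, density = lk$r1 * lk$r2)
  }
  surf <- do.call(rbind, out)
  attr(surf, "n_missing_cells") <- n_missing
  if (n_missing > 0) {
    message(n_missing,
            " cell-year(s) with missing covariate excluded from indices")
  }
  class(surf) <- c("density_surface", "data.frame")
  surf
}

#' Annual abundance index
#'
#' `I_t = sum_s a_s d(s, t)`: the area-weighted total of the predicted
#' density over the extrapolation grid (units of catch, e.g. kg, when
#' density is catch per km^2).
#'
#' @param surface A `density_surface` (columns `year, area_km2, density`).
#' @return data.frame `year, index`.
#' @export
abundance_index <- function(surface) {
  agg <- aggregate(cbind(index = area_km2 * density) ~ year,
                   data = surface[!is.na(surface$density), ], FUN = sum)
  agg[order(agg$year), , drop = FALSE]
}

#' Annual center of gravity
#'
#' Biomass-weighted mean location of the density surface:
#' `z_{t,m} = sum_s z_{s,m} a_s d(s,t) / I_t` for m = northing, easting.
#'
#' @param surface A `density_surface`.
#' @return data.frame `year, easting_km, northing_km` (NA when `I_t = 0`).
#' @export
center_of_gravity <- function(surface) {
  sp <- split(surface[!is.na(surface$density), ],
              surface$year[!is.na(surface$density)])
  out <- do.call(rbind, lapply(sp, function(d) {
    w <- d$area_km2 * d$density
    I <- sum(w)
    if (I <= 0) {
      data.frame(year = d$year[1], easting_km = NA_real_,
                 northing_km = NA_real_)
    } else {
      data.frame(year = d$year[1],
                 easting_km = sum(d$x_km * w) / I,
                 northing_km = sum(d$y_km * w) / I)
    }
  }))
  rownames(out) <- NULL
  out[order(out$year), , drop = FALSE]
}

#' Annual effective area occupied
#'
#' `A_t = I_t / D_t` where `D_t` is the biomass-weighted mean density
#' `sum_s a_s d(s,t)^2 / I_t`, so a uniform surface occupies the whole
#' modeled area and a surface concentrated in one cell occupies that
#' cell's area.  The arithmetic (cell-mean) alternative for `D_t` is
#' available via `weighting = "arithmetic"`.
#'
#' @param surface A `density_surface`.
#' @param weighting `"biomass"` (default) or `"arithmetic"`.
#' @return data.frame `year, eao_km2` (NA when `I_t = 0`).
#' @export
effective_area_occupied <- function(surface,
                                    weighting = c("biomass",
                                                  "arithmetic")) {
  weighting <- match.arg(weighting)
  sp <- split(surface[!is.na(surface$density), ],
              surface$year[!is.na(surface$density)])
  out <- do.call(rbind, lapply(sp, function(d) {
    I <- sum(d$area_km2 * d$density)
    if (I <= 0) return(data.frame(year = d$year[1], eao_km2 = NA_real_))
    D <- if (weighting == "biomass") {
      sum(d$area_km2 * d$density^2) / I
    } else {
      mean(d$density)
    }
    data.frame(year = d$year[1], eao_km2 = I / D)
  }))
  rownames(out) <- NULL
  out[order(out$year), , drop = FALSE]
}

#' Plug-in annual indices from a fitted model
#'
#' Convenience wrapper: predicts the density surface and returns the
#' index, center of gravity, and effective area occupied per year without
#' bias correction.
#'
#' @param fit A `delta_fit`.
#' @param grid_covariates See [predict_density()].
#' @return data.frame `year, index, easting_km, northing_km, eao_km2`.
#' @export
annual_indices <- function(fit, grid_covariates = NULL) {
  surf <- predict_density(fit, grid_covariates = grid_covariates)
  out <- merge(merge(abundance_index(surf), center_of_gravity(surf),
                     by = "year"),
               effective_area_occupied(surf), by = "year")
  out[order(out$year), , drop = FALSE]
}

#' Monte-Carlo mean of a function of a Gaussian vector
#'
#' Averages `fun` over draws from `N(mode, Sigma)`.  This is the
#' retransformation-bias correction primitive: for a nonlinear `fun`,
#' `E[fun(u)]` differs from `fun(E[u])` (for example `E[exp(u)] =
#' exp(mu + sigma^2/2)` for scalar Gaussian `u`).
#'
#' @param fun Function of a numeric vector returning a numeric vector.
#' @param mode Mean vector.
#' @param Sigma Covariance matrix (or scalar variance).
#' @param n_draws Number of draws.
#' @param seed Integer seed.
#' @return List with `mean`, `se` (Monte-Carlo SD of `fun` draws), and
#'   `n_draws`.
#' @export
gaussian_draw_correct <- function(fun, mode, Sigma, n_draws = 500,
                                  seed = 1) {
  mode <- as.numeric(mode)
  n <- length(mode)
  Sigma <- as.matrix(Sigma)
  L <- t(chol(Sigma))
  vals <- with_seed(seed, {
    sapply(seq_len(n_draws), function(i) {
      fun(mode + drop(L %*% rnorm(n)))
    })
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  list(mean = rowMeans(vals), se = apply(vals, 1, sd),
       n_draws = n_draws)
}

#' Bias-corrected annual indices with uncertainty
#'
#' Corrects the plug-in indices for retransformation bias by drawing the
#' random effects from the Gaussian (Laplace) approximation at their mode
#' -- `N(mode, H^-1)` with `H` the inner Hessian of the joint negative
#' log-likelihood -- recomputing the density surface and all three derived
#' quantities for each draw, and reporting the draw mean as the corrected
#' value and the draw SD as its standard error.  Falls back to the
#' plug-in values with a warning if the Hessian is not positive definite.
#'
#' @param fit A `delta_fit`.
#' @param n_draws Number of random-effect draws (default 500).
#' @param seed Integer seed.
#' @param grid_covariates See [predict_density()].
#' @return data.frame per year: `index, se_index, easting_km, se_easting,
#'   northing_km, se_northing, eao_km2, se_eao` plus a `bias_corrected`
#'   attribute/column.
#' @export
bias_correct_indices <- function(fit, n_draws = 500, seed = 1,
                                 grid_covariates = NULL) {
  plug <- annual_indices(fit, grid_covariates = grid_covariates)
  env <- fit$tmb_obj$env
  if (is.null(env$random) || !length(env$random)) {
    plug$bias_corrected <- FALSE
    return(plug)
  }
  H <- env$spHess(env$last.par.best, random = TRUE)
  # dense Cholesky of the inner Hessian: if H = U'U then U^-1 z has
  # covariance H^-1 (the random-effect count is modest at knot meshes)
  U <- tryCatch(chol(as.matrix(Matrix::forceSymmetric(H))),
                error = function(e) NULL)
  if (is.null(U)) {
    warning("inner Hessian not positive definite; returning plug-in ",
            "(uncorrected) indices")
    plug$bias_corrected <- FALSE
    return(plug)
  }
  mode <- env$last.par.best[env$random]
  nre <- length(mode)
  re_names <- names(mode)
  n_knot <- nrow(fit$mesh$knots)
  n_year <- length(fit$years)
  inc <- fit$config$fields

  rebuild <- function(u) {
    f <- fit
    take <- function(nm, len) {
      idx <- which(re_names == nm)
      u[idx]
    }
    if (inc[1]) f$re_modes$omega1 <- take("omega1")
    if (inc[2]) f$re_modes$omega2 <- take("omega2")
    if (inc[3]) f$re_modes$eps1 <- matrix(take("eps1"), n_knot, n_year)
    if (inc[4]) f$re_modes$eps2 <- matrix(take("eps2"), n_knot, n_year)
    f
  }
  draws <- with_seed(seed, {
    lapply(seq_len(n_draws), function(i) {
      u <- mode + backsolve(U, rnorm(nre))
      f <- rebuild(u)
      idx <- annual_indices(f, grid_covariates = grid_covariates)
      as.matrix(idx[, c("index", "easting_km", "northing_km",
                        "eao_km2")])
    })
  })
  arr <- simplify2array(draws)            # year x 4 x n_draws
  m <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), sd)
  out <- data.frame(year = plug$year,
                    index = m[, 1], se_index = s[, 1],
                    easting_km = m[, 2], se_easting = s[, 2],
                    northing_km = m[, 3], se_northing = s[, 3],
                    eao_km2 = m[, 4], se_eao = s[, 4],
                    bias_corrected = TRUE)
  attr(out, "plug_in") <- plug
  attr(out, "n_draws") <- n_draws
  out
}
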