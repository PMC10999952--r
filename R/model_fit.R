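#' Model configuration for the Poisson-link delta GLMM
#'
#' @param covariate Name of a single covariate column to include (the
#'   workflow fits one covariate per model), or `NULL` for the base
#'   spatio-temporal model.
#' @param form Basis form for the covariate: `"linear"` or `"spline2df"`.
#' @param transform `"identity"` or `"log1p"` applied before z-scoring.
#' @param covariate_in_p2 Should the covariate also enter the second linear
#'   predictor (catch-rate component)?  Default `TRUE`.
#' @param n_knots,buffer_km,grid_spacing_km,mesh_seed Mesh settings passed
#'   to [build_mesh()].
#' @param fields Logical vector of length 4 naming which random fields are
#'   estimated: `omega1`, `omega2`, `eps1`, `eps2`.
#' @param estimate_range Estimate the decorrelation range (log scale)?  If
#'   `FALSE`, the range is fixed at `range_km`.
#' @param range_km Fixed (or starting) decorrelation range in km.
#' @param grad_tol Convergence requires the maximum absolute gradient of
#'   the log-marginal-likelihood to fall below this value.
#' @param max_restarts Number of optimizer restarts from the incumbent when
#'   the gradient criterion is not yet met.
#' @param seed Seed recorded with the fit (mesh building, fold draws).
#' @return A `delta_model_config` list.
#' @export
delta_model_config <- function(covariate = NULL,
                               form = c("linear", "spline2df"),
                               transform = c("identity", "log1p"),
                               covariate_in_p2 = TRUE,
                               n_knots = 50, buffer_km = 25,
                               grid_spacing_km = 10, mesh_seed = 1,
                               fields = c(omega1 = TRUE, omega2 = TRUE,
                                          eps1 = TRUE, eps2 = TRUE),
                               estimate_range = TRUE, range_km = 150,
                               grad_tol = 1e-3, max_restarts = 3,
                               seed = 1) {
  form <- match.arg(form)
  transform <- match.arg(transform)
  stopifnot(length(fields) == 4)
  structure(list(covariate = covariate, form = form, transform = transform,
                 covariate_in_p2 = covariate_in_p2, n_knots = n_knots,
                 buffer_km = buffer_km, grid_spacing_km = grid_spacing_km,
                 mesh_seed = mesh_seed, fields = as.logical(fields),
                 estimate_range = estimate_range, range_km = range_km,
                 grad_tol = grad_tol, max_restarts = max_restarts,
                 seed = seed),
            class = "delta_model_config")
}

#' Poisson-link functions
#'
#' Maps the two linear predictors and the effort offset to encounter
#' probability and positive catch rate:
#' `r1 = 1 - exp(-a exp(p1))`, `r2 = a exp(p1) / r1 * exp(p2)`, so that
#' the expected catch obeys `r1 * r2 = a * exp(p1 + p2)`.  Computation is
#' carried out in log space for numerical stability at extreme `p1`.
#'
#' @param p1,p2 Linear predictors (log number density; log catch per
#'   individual).
#' @param area_swept Effort `a > 0` (km^2).
#' @return A list with components `r1` and `r2`.
#' @export
poisson_link <- function(p1, p2, area_swept) {
  if (any(area_swept <= 0)) stop("area_swept must be > 0")
  log_m <- log(area_swept) + p1      # log(a * exp(p1))
  m <- exp(log_m)
  # log(1 - exp(-m)) via log1p; for tiny m use log(m) - m/2 expansion
  log_r1 <- ifelse(m > 1e-8, log1p(-exp(-m)), log_m - m / 2)
  r1 <- exp(log_r1)
  r2 <- exp(log_m - log_r1 + p2)
  list(r1 = r1, r2 = r2)
}

#' Observation log-likelihood of the delta-gamma model
#'
#' Zero catches contribute `log(1 - r1)`; positive catches contribute
#' `log(r1)` plus a gamma log-density with mean `r2` and coefficient of
#' variation `cv` (shape `1/cv^2`, scale `r2 * cv^2`).
#'
#' @param catch Observed catch, `>= 0`.
#' @param r1,r2 Encounter probability and positive catch rate.
#' @param cv Gamma coefficient of variation, `> 0`.
#' @return Log-likelihood per record.
#' @export
observation_loglik <- function(catch, r1, r2, cv) {
  if (any(catch < 0)) stop("catch must be >= 0")
  if (cv <= 0) stop("cv must be > 0")
  shape <- 1 / cv^2
  ifelse(catch == 0,
         log1p(-r1),
         log(r1) + dgamma(catch, shape = shape, scale = r2 * cv^2,
                          log = TRUE))
}

## --- internal TMB plumbing ----------------------------------------------

tmb_data <- function(stations, mesh, basis, config) {
  years <- sort(unique(stations$year))
  X <- if (is.null(basis)) matrix(0, nrow(stations), 0L) else
    unname(predict(basis, stations[[basis$name]]))
  X2 <- if (!is.null(basis) && config$covariate_in_p2) X else
    matrix(0, nrow(stations), 0L)
  list(
    dat = list(
      catch_obs = as.numeric(stations$catch),
      is_pos = as.integer(stations$catch > 0),
      log_area = log(as.numeric(stations$area_swept)),
      year_i = match(stations$year, years) - 1L,
      knot_i = as.integer(mesh$station_to_knot) - 1L,
      X1 = X, X2 = X2,
      D = unname(mesh$distances),
      kappa_scale = matern_kappa_scale(),
      n_year = length(years),
      include_field = as.integer(config$fields)
    ),
    years = years
  )
}

tmb_start <- function(stations, years, n_knot, p1cols, p2cols, config) {
  a1 <- vapply(years, function(y) {
    d <- stations$catch[stations$year == y] /
      stations$area_swept[stations$year == y]
    log(mean(d) + 1e-3)
  }, numeric(1))
  list(alpha1 = a1, alpha2 = rep(0, length(years)),
       gamma1 = rep(0, p1cols), gamma2 = rep(0, p2cols),
       log_sd = rep(log(0.5), 4), log_range = log(config$range_km),
       log_cv = 0,
       omega1 = rep(0, n_knot), omega2 = rep(0, n_knot),
       eps1 = matrix(0, n_knot, length(years)),
       eps2 = matrix(0, n_knot, length(years)))
}

tmb_map <- function(config, p1cols, p2cols, n_knot, n_year) {
  map <- list()
  inc <- config$fields
  sd_fac <- seq_len(4)
  if (!inc[1]) { map$omega1 <- factor(rep(NA, n_knot)); sd_fac[1] <- NA }
  if (!inc[2]) { map$omega2 <- factor(rep(NA, n_knot)); sd_fac[2] <- NA }
  if (!inc[3]) { map$eps1 <- factor(rep(NA, n_knot * n_year)); sd_fac[3] <- NA }
  if (!inc[4]) { map$eps2 <- factor(rep(NA, n_knot * n_year)); sd_fac[4] <- NA }
  if (anyNA(sd_fac)) map$log_sd <- factor(sd_fac)
  if (!config$estimate_range || !any(inc)) map$log_range <- factor(NA)
  map
}

make_tmb_obj <- function(stations, mesh, basis, config, start = NULL) {
  td <- tmb_data(stations, mesh, basis, config)
  p1cols <- ncol(td$dat$X1)
  p2cols <- ncol(td$dat$X2)
  par0 <- tmb_start(stations, td$years, nrow(mesh$knots),
                    p1cols, p2cols, config)
  if (!is.null(start)) par0[names(start)] <- start
  map <- tmb_map(config, p1cols, p2cols, nrow(mesh$knots),
                 length(td$years))
  random <- c("omega1", "omega2", "eps1", "eps2")[config$fields]
  obj <- TMB::MakeADFun(td$dat, par0, map = map,
                        random = if (length(random)) random else NULL,
                        DLL = "sockidx", silent = TRUE)
  list(obj = obj, years = td$years)
}

# extract random-effect modes (zero-filled for excluded fields)
re_modes_from_obj <- function(obj, n_knot, n_year) {
  pl <- obj$env$parList(par = obj$env$last.par.best)
  shape <- function(x, mat) {
    if (is.null(x) || !length(x)) {
      if (mat) matrix(0, n_knot, n_year) else rep(0, n_knot)
    } else if (mat) matrix(x, n_knot, n_year) else as.numeric(x)
  }
  structure(list(omega1 = shape(pl$omega1, FALSE),
                 omega2 = shape(pl$omega2, FALSE),
                 eps1 = shape(pl$eps1, TRUE),
                 eps2 = shape(pl$eps2, TRUE)),
            class = "field_realization")
}

## --- fitting -------------------------------------------------------------

#' Fit the Poisson-link delta GLMM
#'
#' Maximizes the Laplace-approximated marginal likelihood over the fixed
#' parameters (year intercepts, covariate coefficients, log-scale variance
#' parameters, log CV) with the random fields integrated out.  Convergence
#' is declared when the maximum absolute gradient of the log-marginal
#' likelihood falls below `config$grad_tol` after at most
#' `config$max_restarts` optimizer restarts; non-convergence is reported,
#' never silently accepted.
#'
#' @param stations Station data.frame (see [validate_stations()]); the
#'   covariate named in `config`, if any, must be complete.
#' @param config A [delta_model_config()].
#' @param mesh Optional pre-built [build_mesh()] mesh (rebuilt from
#'   `config` when `NULL`).
#' @return A `delta_fit` object with year intercepts (`alpha1`, `alpha2`),
#'   covariate coefficients with SEs (`gamma1`, `gamma2`, `gamma_cov`),
#'   `field_params`, `gamma_obs_cv`, random-effect modes (`re_modes`),
#'   `logml`, `max_abs_grad`, `converged`, flagged zero-encounter years,
#'   and the underlying TMB object for downstream prediction.
#' @export
fit_delta_model <- function(stations, config = delta_model_config(),
                            mesh = NULL) {
  stations <- validate_stations(stations)
  years <- sort(unique(stations$year))
  if (length(years) < 2) stop("need at least 2 years of data")
  if (is.null(mesh)) {
    mesh <- build_mesh(stations, n_knots = config$n_knots,
                       buffer_km = config$buffer_km,
                       grid_spacing_km = config$grid_spacing_km,
                       seed = config$mesh_seed)
  } else {
    mesh$station_to_knot <- assign_to_knot(
      mesh, cbind(stations$easting_km, stations$northing_km))
  }
  basis <- NULL
  if (!is.null(config$covariate)) {
    if (!config$covariate %in% names(stations)) {
      stop("covariate '", config$covariate, "' not in station table")
    }
    basis <- build_basis(stations[[config$covariate]], config$form,
                         config$transform, name = config$covariate)
  }
  enc_by_year <- tapply(stations$catch > 0, stations$year, any)
  flagged_years <- as.numeric(names(enc_by_year))[!enc_by_year]
  if (length(flagged_years)) {
    warning("year(s) without encounters (intercept weakly identified): ",
            paste(flagged_years, collapse = ", "))
  }

  mk <- make_tmb_obj(stations, mesh, basis, config)
  obj <- mk$obj
  opt <- nlminb(obj$par, obj$fn, obj$gr,
                control = list(iter.max = 500, eval.max = 700))
  g <- obj$gr(opt$par)
  restarts <- 0
  while (max(abs(g)) > config$grad_tol &&
         restarts < config$max_restarts) {
    opt <- nlminb(opt$par, obj$fn, obj$gr,
                  control = list(iter.max = 500, eval.max = 700))
    g <- obj$gr(opt$par)
    restarts <- restarts + 1
  }
  max_abs_grad <- max(abs(g))
  converged <- is.finite(opt$objective) && max_abs_grad < config$grad_tol
  if (!converged) {
    warning("fit did not meet the gradient criterion: max|grad| = ",
            format(max_abs_grad))
  }

  sdr <- TMB::sdreport(obj, getReportCovariance = FALSE)
  est <- obj$env$last.par.best
  pl <- obj$env$parList(opt$par, par = est)
  nm <- names(opt$par)
  # parList() returns mapped-off entries at their starting values; report
  # excluded fields as variance zero
  inc <- config$fields
  sds <- exp(as.numeric(pl$log_sd))
  sds[!inc] <- 0
  fp <- field_params(sd_omega1 = sds[1], sd_omega2 = sds[2],
                     sd_eps1 = sds[3], sd_eps2 = sds[4],
                     range_km = exp(pl$log_range))

  cf <- sdr$cov.fixed
  gidx1 <- which(nm == "gamma1")
  gidx2 <- which(nm == "gamma2")
  se <- sqrt(pmax(diag(cf), 0))
  gamma_raw <- NULL
  if (!is.null(basis) && basis$form == "linear") {
    gamma_raw <- c(p1 = unname(pl$gamma1) / basis$scale,
                   p2 = if (length(pl$gamma2))
                     unname(pl$gamma2) / basis$scale else NA_real_)
  }

  fit <- structure(list(
    years = mk$years,
    alpha1 = setNames(as.numeric(pl$alpha1), mk$years),
    alpha2 = setNames(as.numeric(pl$alpha2), mk$years),
    gamma1 = as.numeric(pl$gamma1),
    gamma2 = as.numeric(pl$gamma2),
    gamma1_se = unname(se[gidx1]),
    gamma2_se = unname(se[gidx2]),
    gamma_cov = cf[c(gidx1, gidx2), c(gidx1, gidx2), drop = FALSE],
    gamma_raw = gamma_raw,
    field_params = fp,
    gamma_obs_cv = exp(pl$log_cv),
    re_modes = re_modes_from_obj(obj, nrow(mesh$knots),
                                 length(mk$years)),
    logml = -opt$objective,
    max_abs_grad = max_abs_grad,
    converged = converged,
    restarts = restarts,
    flagged_years = flagged_years,
    basis = basis,
    mesh = mesh,
    config = config,
    data = stations,
    n_fixed = length(opt$par),
    tmb_obj = obj,
    sdreport = sdr
  ), class = "delta_fit")
  fit
}

#' @export
print.delta_fit <- function(x, ...) {
  cat("Poisson-link delta GLMM fit\n")
  cat("  records:", nrow(x$data), " years:", length(x$years),
      " knots:", nrow(x$mesh$knots), "\n")
  if (!is.null(x$basis)) {
    cat("  covariate:", x$basis$name, paste0("(", x$basis$form, ")"),
        " gamma1 =", paste(round(x$gamma1, 4), collapse = ", "), "\n")
  }
  fp <- x$field_params
  cat(sprintf("  sd(omega) = %.3f / %.3f  sd(eps) = %.3f / %.3f  range = %.0f km\n",
              fp$sd_omega1, fp$sd_omega2, fp$sd_eps1, fp$sd_eps2,
              fp$range_km))
  cat(sprintf("  gamma CV = %.3f  logml = %.3f  max|grad| = %.2g (%s)\n",
              x$gamma_obs_cv, x$logml, x$max_abs_grad,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Linear predictors at stations
#'
#' Assembles `p1 = alpha1[t] + omega1[s] + eps1[s,t] + X gamma1` (and the
#' analogous `p2`) at the fitted parameter values and random-effect modes.
#'
#' @param fit A `delta_fit`.
#' @param stations Station table (defaults to the training data).
#' @return A list with vectors `p1` and `p2`.
#' @export
linear_predictors <- function(fit, stations = fit$data) {
  yi <- match(stations$year, fit$years)
  if (anyNA(yi)) stop("stations contain years absent from the fit")
  si <- assign_to_knot(fit$mesh,
                       cbind(stations$easting_km, stations$northing_km))
  inc <- fit$config$fields
  p1 <- fit$alpha1[yi] +
    (if (inc[1]) fit$re_modes$omega1[si] else 0) +
    (if (inc[3]) fit$re_modes$eps1[cbind(si, yi)] else 0)
  p2 <- fit$alpha2[yi] +
    (if (inc[2]) fit$re_modes$omega2[si] else 0) +
    (if (inc[4]) fit$re_modes$eps2[cbind(si, yi)] else 0)
  if (!is.null(fit$basis)) {
    X <- predict(fit$basis, stations[[fit$basis$name]])
    p1 <- p1 + drop(X %*% fit$gamma1)
    if (length(fit$gamma2)) p2 <- p2 + drop(X %*% fit$gamma2)
  }
  list(p1 = unname(p1), p2 = unname(p2))
}

#' Laplace-approximated marginal log-likelihood at given fixed parameters
#'
#' Runs the inner Newton optimization over all random effects at the
#' supplied fixed-parameter values and returns the Laplace approximation
#' `logml = joint at mode + 0.5 log det(2 pi H^-1)` together with the
#' random-effect modes.
#'
#' @param fixed_params Named list: `alpha1`, `alpha2` (per year), optional
#'   `gamma1`, `gamma2`, `field_params` (a [field_params()]), `cv`.
#' @param stations Station table.
#' @param mesh A `survey_mesh`.
#' @param basis Optional `covariate_basis` aligned with `gamma1`/`gamma2`.
#' @param config A [delta_model_config()]; its `fields` entry selects which
#'   random fields are present.
#' @return List with `logml` and `re_modes`.
#' @export
laplace_marginal_loglik <- function(fixed_params, stations, mesh,
                                    basis = NULL,
                                    config = delta_model_config()) {
  stations <- validate_stations(stations)
  mesh$station_to_knot <- assign_to_knot(
    mesh, cbind(stations$easting_km, stations$northing_km))
  fp <- fixed_params$field_params
  if (is.null(fp)) fp <- field_params()
  config$range_km <- fp$range_km
  config$estimate_range <- FALSE
  if (!is.null(basis) && is.null(config$covariate)) {
    config$covariate <- basis$name
  }
  start <- list(alpha1 = fixed_params$alpha1,
                alpha2 = fixed_params$alpha2,
                log_sd = log(pmax(c(fp$sd_omega1, fp$sd_omega2,
                                    fp$sd_eps1, fp$sd_eps2), 1e-12)),
                log_cv = log(fixed_params$cv %||% 1))
  if (!is.null(fixed_params$gamma1)) start$gamma1 <- fixed_params$gamma1
  if (!is.null(fixed_params$gamma2)) start$gamma2 <- fixed_params$gamma2
  mk <- make_tmb_obj(stations, mesh, basis, config, start = start)
  logml <- -as.numeric(mk$obj$fn(mk$obj$par))
  list(logml = logml,
       re_modes = re_modes_from_obj(mk$obj, nrow(mesh$knots),
                                    length(mk$years)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson residuals of the two model components
#'
#' Encounter component: `(1{catch>0} - r1) / sqrt(r1 (1 - r1))` for all
#' records.  Positive component (encountered records only):
#' `(catch - r2) / (r2 cv)`.  Records where `r1` is numerically 0 or 1 get
#' `NA` with the count reported as an attribute.
#'
#' @param fit A `delta_fit`.
#' @param stations Station table (defaults to training data).
#' @return data.frame with columns `encounter` and `positive` (NA for
#'   zero-catch records); attribute `n_undefined`.
#' @export
pearson_residuals <- function(fit, stations = fit$data) {
  lp <- linear_predictors(fit, stations)
  lk <- poisson_link(lp$p1, lp$p2, stations$area_swept)
  cv <- fit$gamma_obs_cv
  enc <- as.numeric(stations$catch > 0)
  undef <- lk$r1 <= 0 | lk$r1 >= 1
  r_enc <- ifelse(undef, NA_real_,
                  (enc - lk$r1) / sqrt(lk$r1 * (1 - lk$r1)))
  r_pos <- ifelse(enc == 1, (stations$catch - lk$r2) / (lk$r2 * cv),
                  NA_real_)
  structure(data.frame(encounter = r_enc, positive = r_pos),
            n_undefined = sum(undef))
}

#' Cross-validate observed-versus-predicted density
#'
#' Simple random partition of the records into `n_folds` folds; the model
#' is refit on each training set (same mesh layout) and held-out catches
#' are regressed on their predicted expectations `r1 * r2`.  Reports the
#' regression slope, intercept, and R-squared per fold, pooled over folds,
#' and in-sample.
#'
#' @param stations Station table.
#' @param config A [delta_model_config()].
#' @param n_folds Number of folds (>= 2).
#' @param seed Seed for the fold assignment.
#' @return A list with `in_sample`, `folds` (data.frame), and `pooled`.
#' @export
cross_validate <- function(stations, config = delta_model_config(),
                           n_folds = 3, seed = 1) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  stations <- validate_stations(stations)
  mesh <- build_mesh(stations, n_knots = config$n_knots,
                     buffer_km = config$buffer_km,
                     grid_spacing_km = config$grid_spacing_km,
                     seed = config$mesh_seed)
  full <- fit_delta_model(stations, config, mesh = mesh)
  score <- function(obs, pred) {
    m <- lm(obs ~ pred)
    c(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
      r2 = summary(m)$r.squared)
  }
  lp <- linear_predictors(full, stations)
  lk <- poisson_link(lp$p1, lp$p2, stations$area_swept)
  in_sample <- score(stations$catch, lk$r1 * lk$r2)

  fold_id <- with_seed(seed,
                       sample(rep_len(seq_len(n_folds), nrow(stations))))
  rows <- list(); pooled_obs <- c(); pooled_pred <- c()
  for (k in seq_len(n_folds)) {
    test <- fold_id == k
    train <- stations[!test, , drop = FALSE]
    fit_k <- fit_delta_model(train, config, mesh = mesh)
    lp_k <- linear_predictors(fit_k, stations[test, , drop = FALSE])
    lk_k <- poisson_link(lp_k$p1, lp_k$p2, stations$area_swept[test])
    obs <- stations$catch[test]
    pred <- lk_k$r1 * lk_k$r2
    ok <- any(obs > 0)
    s <- if (ok) score(obs, pred) else c(slope = NA, intercept = NA,
                                         r2 = NA)
    rows[[k]] <- data.frame(fold = k, n = sum(test), t(s),
                            usable = ok)
    if (ok) { pooled_obs <- c(pooled_obs, obs)
              pooled_pred <- c(pooled_pred, pred) }
  }
  folds <- do.call(rbind, rows)
  if (any(!folds$usable)) {
    warning("fold(s) without positive catches excluded from pooled R2: ",
            paste(folds$fold[!folds$usable], collapse = ", "))
  }
  pooled <- if (length(pooled_obs)) score(pooled_obs, pooled_pred) else
    c(slope = NA, intercept = NA, r2 = NA)
  list(in_sample = in_sample, folds = folds, pooled = pooled,
       seed = seed)
}
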