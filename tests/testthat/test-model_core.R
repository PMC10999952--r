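test_that("Poisson link: closed forms, limits, and the catch identity", {
  lk <- poisson_link(0, 0, 1)
  expect_equal(lk$r1, 1 - exp(-1), tolerance = 1e-12)
  expect_equal(lk$r2, 1 / (1 - exp(-1)), tolerance = 1e-12)
  # p1 -> -Inf: encounter probability and expected catch vanish
  lk_lo <- poisson_link(-40, 0, 1)
  expect_lt(lk_lo$r1, 1e-15)
  expect_lt(lk_lo$r1 * lk_lo$r2, 1e-15)
  # r1 * r2 = a * exp(p1 + p2) for random triples
  set.seed(20)
  p1 <- runif(1e4, -8, 6); p2 <- runif(1e4, -4, 4)
  a <- runif(1e4, 0.01, 2)
  lk <- poisson_link(p1, p2, a)
  expect_lt(max(abs(lk$r1 * lk$r2 - a * exp(p1 + p2)) /
                  (a * exp(p1 + p2))), 1e-12)
  expect_true(all(lk$r1 > 0 & lk$r1 <= 1))
  # strictly below 1 whenever a exp(p1) is moderate enough to resolve
  mod <- a * exp(p1) < 30
  expect_true(all(lk$r1[mod] < 1))
  expect_error(poisson_link(0, 0, 0), "area_swept")
})

test_that("observation log-likelihood: zero, exponential, and peak cases", {
  expect_equal(observation_loglik(0, 0.5, 2, 1), log(0.5))
  # catch = 2, r2 = 2, cv = 1 is an exponential with scale 2
  expect_equal(observation_loglik(2, 0.6, 2, 1),
               log(0.6) + log(0.5 * exp(-1)), tolerance = 1e-12)
  # density concentrates at r2 as cv shrinks
  ll <- sapply(c(1, 0.5, 0.1, 0.02),
               function(cv) observation_loglik(2, 0.6, 2, cv))
  expect_true(all(diff(ll) > 0))
  expect_error(observation_loglik(-1, 0.5, 1, 1), "catch")
})

test_that("linear predictors assemble intercepts, fields, and basis terms", {
  s <- desk_sim()
  fit <- desk_fit()
  lp <- linear_predictors(fit)
  st <- fit$data
  yi <- match(st$year, fit$years)
  si <- fit$mesh$station_to_knot
  manual <- fit$alpha1[yi] + fit$re_modes$omega1[si] +
    fit$re_modes$eps1[cbind(si, yi)]
  expect_equal(lp$p1, unname(manual), tolerance = 1e-12)

  # with a spline covariate the contribution is the basis-row product
  cfg <- delta_model_config(covariate = "temp20", form = "spline2df",
                            n_knots = 25, grid_spacing_km = 20)
  fitc <- cached("desk_fit_temp", fit_delta_model(s$stations, cfg,
                                                  mesh = s$mesh))
  lpc <- linear_predictors(fitc)
  B <- predict(fitc$basis, st$temp20)
  manual_c <- fitc$alpha1[yi] + fitc$re_modes$omega1[si] +
    fitc$re_modes$eps1[cbind(si, yi)] + drop(B %*% fitc$gamma1)
  expect_equal(lpc$p1, unname(manual_c), tolerance = 1e-10)
})

test_that("degenerate random effects: Laplace equals the fixed-effect loglik", {
  st <- square_stations(n_side = 6, n_years = 2, seed = 31)
  mesh <- build_mesh(st, n_knots = 6, buffer_km = 150, seed = 1)
  cfg <- delta_model_config(fields = c(FALSE, FALSE, FALSE, FALSE),
                            n_knots = 6)
  fx <- list(alpha1 = c(0.4, 0.2), alpha2 = c(0.1, -0.1),
             field_params = field_params(0, 0, 0, 0, 150), cv = 0.9)
  got <- laplace_marginal_loglik(fx, st, mesh, config = cfg)
  yi <- st$year
  manual <- sum(obs_loglik_manual(st$catch, fx$alpha1[yi], fx$alpha2[yi],
                                  st$area_swept, 0.9))
  expect_equal(got$logml, manual, tolerance = 1e-9)

  # duplicating every record exactly doubles the loglik in this case
  st2 <- rbind(st, transform(st, station_id = paste0(station_id, "b")))
  got2 <- laplace_marginal_loglik(fx, st2, mesh, config = cfg)
  expect_equal(got2$logml, 2 * manual, tolerance = 1e-9)
})

test_that("Laplace matches adaptive Gauss-Hermite with 1 random effect", {
  st <- square_stations(n_side = 11, n_years = 1, spacing = 10,
                        seed = 52)[1:120, ]
  sd_o <- 0.5; alpha1 <- 0.8; alpha2 <- 0.1; cv <- 0.8
  st$catch <- with_test_seed(61, {
    u <- rnorm(1, 0, sd_o)
    m <- st$area_swept * exp(alpha1 + u)
    r1 <- 1 - exp(-m)
    r2 <- m / r1 * exp(alpha2)
    rbinom(nrow(st), 1, r1) *
      rgamma(nrow(st), 1 / cv^2, scale = r2 * cv^2)
  })
  mesh <- build_mesh(st, n_knots = 1, buffer_km = 150, seed = 1)
  cfg <- delta_model_config(fields = c(TRUE, FALSE, FALSE, FALSE),
                            n_knots = 1)
  fx <- list(alpha1 = alpha1, alpha2 = alpha2,
             field_params = field_params(sd_o, 0, 0, 0, 150), cv = cv)
  got <- laplace_marginal_loglik(fx, st, mesh, config = cfg)
  Sigma <- matrix(sd_o^2 * (1 + 1e-8), 1, 1)
  jn <- toy_jnll(st$catch, rep(alpha1, nrow(st)),
                 rep(alpha2, nrow(st)), st$area_swept, cv,
                 rep(1, nrow(st)), Sigma)
  oracle <- gh_adaptive_logml(jn, d = 1)
  expect_equal(got$logml, oracle, tolerance = 1e-4)
})

test_that("Laplace matches adaptive tensor quadrature with 2 random effects", {
  st <- square_stations(n_side = 10, n_years = 1, spacing = 40,
                        seed = 53)
  mesh <- build_mesh(st, n_knots = 2, buffer_km = 300, seed = 1)
  sd_o <- 0.6; alpha1 <- 0.5; alpha2 <- 0; cv <- 0.7
  C <- matern_direct(mesh$distances, 120)
  st$catch <- with_test_seed(62, {
    u <- drop(t(chol(sd_o^2 * C)) %*% rnorm(2))
    m <- st$area_swept * exp(alpha1 + u[mesh$station_to_knot])
    r1 <- 1 - exp(-m)
    r2 <- m / r1 * exp(alpha2)
    rbinom(nrow(st), 1, r1) *
      rgamma(nrow(st), 1 / cv^2, scale = r2 * cv^2)
  })
  cfg <- delta_model_config(fields = c(TRUE, FALSE, FALSE, FALSE),
                            n_knots = 2, estimate_range = FALSE,
                            range_km = 120)
  fx <- list(alpha1 = alpha1, alpha2 = alpha2,
             field_params = field_params(sd_o, 0, 0, 0, 120), cv = cv)
  got <- laplace_marginal_loglik(fx, st, mesh, config = cfg)
  jn <- toy_jnll(st$catch, rep(alpha1, nrow(st)),
                 rep(alpha2, nrow(st)), st$area_swept, cv,
                 mesh$station_to_knot, sd_o^2 * C)
  oracle <- gh_adaptive_logml(jn, d = 2)
  expect_equal(got$logml, oracle, tolerance = 1e-3)
})

test_that("fit recovers year intercepts without fields, and is exchangeable", {
  sc <- sim_scenario(n_years = 3, stations_per_year = 150,
                     fields = field_params(0, 0, 0, 0, 150),
                     alpha1 = c(1.2, 1.8, 1.5), alpha2 = c(0, 0.2, -0.1),
                     n_knots = 8, seed = 77)
  s <- simulate_survey(sc)
  cfg <- delta_model_config(fields = c(FALSE, FALSE, FALSE, FALSE),
                            n_knots = 8)
  fit <- fit_delta_model(s$stations, cfg, mesh = s$mesh)
  expect_true(fit$converged)
  sf <- summary(fit$sdreport, select = "fixed")
  a1 <- sf[rownames(sf) == "alpha1", ]
  expect_true(all(abs(a1[, 1] - c(1.2, 1.8, 1.5)) < 3 * a1[, 2]))

  # permuting record order leaves the fit unchanged
  perm <- with_test_seed(5, sample(nrow(s$stations)))
  fit_p <- fit_delta_model(s$stations[perm, ], cfg, mesh = s$mesh)
  expect_equal(fit_p$logml, fit$logml, tolerance = 1e-6)
  expect_equal(fit_p$alpha1, fit$alpha1, tolerance = 1e-5)

  # duplicated data: identical estimates, exactly doubled loglik
  dup <- rbind(s$stations,
               transform(s$stations,
                         station_id = paste0(station_id, "b")))
  fit_d <- fit_delta_model(dup, cfg, mesh = s$mesh)
  expect_equal(fit_d$alpha1, fit$alpha1, tolerance = 1e-4)
  expect_equal(fit_d$logml, 2 * fit$logml, tolerance = 1e-5)
})

test_that("reported optimum has a small finite-difference gradient", {
  fit <- desk_fit()
  expect_lt(fit$max_abs_grad, 1e-3)
  obj <- fit$tmb_obj
  par_hat <- obj$env$last.par.best[-obj$env$random]
  g_fd <- numDeriv::grad(function(p) as.numeric(obj$fn(p)), par_hat,
                         method = "simple",
                         method.args = list(eps = 1e-5))
  expect_lt(max(abs(g_fd)), 0.05)
})

test_that("Pearson residuals: closed forms and calibration", {
  fit <- desk_fit()
  res <- pearson_residuals(fit)
  st <- fit$data
  lp <- linear_predictors(fit)
  lk <- poisson_link(lp$p1, lp$p2, st$area_swept)
  i <- which(st$catch > 0)[1]
  expect_equal(res$encounter[i],
               (1 - lk$r1[i]) / sqrt(lk$r1[i] * (1 - lk$r1[i])))
  expect_equal(res$positive[i],
               (st$catch[i] - lk$r2[i]) / (lk$r2[i] * fit$gamma_obs_cv))
  # a record with catch == r2 has zero positive residual by construction
  expect_equal((lk$r2[i] - lk$r2[i]) / (lk$r2[i] * fit$gamma_obs_cv), 0)
  # encounter residuals are near unit variance at the fitted parameters
  expect_lt(abs(var(res$encounter, na.rm = TRUE) - 1), 0.25)
  expect_identical(attr(res, "n_undefined"), 0L)
})

test_that("cross-validation: threefold refits and R-squared bookkeeping", {
  s <- desk_sim()
  cfg <- delta_model_config(n_knots = 15, grid_spacing_km = 20)
  cv <- cached("desk_cv", cross_validate(s$stations, cfg, n_folds = 3,
                                         seed = 5))
  expect_equal(nrow(cv$folds), 3)
  expect_true(all(cv$folds$usable))
  expect_true(cv$in_sample["r2"] > 0 && cv$in_sample["r2"] <= 1)
  expect_true(cv$pooled["r2"] > 0 && cv$pooled["r2"] <= 1)
  # the model fits its own training data at least as well as held-out data
  expect_gt(cv$in_sample["r2"], cv$pooled["r2"] - 0.1)
})
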