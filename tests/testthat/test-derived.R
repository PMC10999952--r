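# minimal hand-built fit object for pure-arithmetic surface checks
toy_fit <- function(mesh, alpha1, alpha2, years = seq_along(alpha1),
                    omega1 = NULL, eps1 = NULL) {
  nk <- nrow(mesh$knots)
  ny <- length(years)
  fields <- c(!is.null(omega1), FALSE, !is.null(eps1), FALSE)
  structure(list(
    years = years,
    alpha1 = setNames(alpha1, years), alpha2 = setNames(alpha2, years),
    gamma1 = numeric(0), gamma2 = numeric(0), basis = NULL,
    re_modes = list(omega1 = omega1 %||% rep(0, nk),
                    omega2 = rep(0, nk),
                    eps1 = eps1 %||% matrix(0, nk, ny),
                    eps2 = matrix(0, nk, ny)),
    mesh = mesh,
    config = delta_model_config(fields = fields)
  ), class = "delta_fit")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

rand_surface <- function(n_cells = 40, n_years = 3, seed = 14) {
  with_test_seed(seed, {
    structure(data.frame(
      cell_id = rep(seq_len(n_cells), n_years),
      x_km = rep(runif(n_cells, 0, 500), n_years),
      y_km = rep(runif(n_cells, 6000, 6500), n_years),
      area_km2 = rep(runif(n_cells, 50, 150), n_years),
      year = rep(seq_len(n_years), each = n_cells),
      density = rgamma(n_cells * n_years, 1.5, 0.5)),
      class = c("density_surface", "data.frame"))
  })
}

test_that("density prediction: unit density at zero parameters, hand chain", {
  st <- square_stations(n_side = 3, n_years = 2, spacing = 60)
  mesh <- build_mesh(st, n_knots = 2, buffer_km = 120,
                     grid_spacing_km = 30, seed = 1)
  f0 <- toy_fit(mesh, alpha1 = c(0, 0), alpha2 = c(0, 0))
  surf <- predict_density(f0)
  expect_true(all(abs(surf$density - 1) < 1e-12))
  # p1 = log 2, p2 = 0 gives d = 2 by the identity r1 r2 = exp(p1 + p2)
  f2 <- toy_fit(mesh, alpha1 = c(log(2), log(2)), alpha2 = c(0, 0))
  expect_true(all(abs(predict_density(f2)$density - 2) < 1e-12))
  # two-knot toy with a spatial field: full Eq chain by hand
  om <- c(0.5, -0.3)
  ff <- toy_fit(mesh, alpha1 = c(0.2, 0.1), alpha2 = c(0, 0.3),
                omega1 = om)
  surf_f <- predict_density(ff)
  k <- mesh$grid$knot_id[match(surf_f$cell_id, mesh$grid$cell_id)]
  p1 <- surf_f$year * 0 + c(0.2, 0.1)[match(surf_f$year, 1:2)] + om[k]
  p2 <- c(0, 0.3)[match(surf_f$year, 1:2)]
  m <- exp(p1); r1 <- 1 - exp(-m); r2 <- m / r1 * exp(p2)
  expect_equal(surf_f$density, r1 * r2, tolerance = 1e-12)
})

test_that("index, COG, EAO match brute-force oracles and closed cases", {
  surf <- rand_surface()
  idx <- abundance_index(surf)
  cog <- center_of_gravity(surf)
  eao <- effective_area_occupied(surf)
  for (t in 1:3) {
    d <- surf[surf$year == t, ]
    I <- 0; zx <- 0; zy <- 0; q <- 0
    for (i in seq_len(nrow(d))) {            # deliberate brute force
      I <- I + d$area_km2[i] * d$density[i]
      zx <- zx + d$x_km[i] * d$area_km2[i] * d$density[i]
      zy <- zy + d$y_km[i] * d$area_km2[i] * d$density[i]
      q <- q + d$area_km2[i] * d$density[i]^2
    }
    expect_equal(idx$index[idx$year == t], I, tolerance = 1e-12)
    expect_equal(cog$easting_km[cog$year == t], zx / I,
                 tolerance = 1e-12)
    expect_equal(cog$northing_km[cog$year == t], zy / I,
                 tolerance = 1e-12)
    expect_equal(eao$eao_km2[eao$year == t], I / (q / I),
                 tolerance = 1e-12)
  }

  # uniform density: index = d * area, COG at centroid, EAO = total area
  u <- surf[surf$year == 1, ]
  u$density <- 2.5
  class(u) <- c("density_surface", "data.frame")
  tot <- sum(u$area_km2)
  expect_equal(abundance_index(u)$index, 2.5 * tot)
  expect_equal(center_of_gravity(u)$easting_km,
               sum(u$x_km * u$area_km2) / tot)
  expect_equal(effective_area_occupied(u)$eao_km2, tot)

  # all biomass in one 100 km^2 cell: EAO equals that cell's area
  one <- u
  one$density <- 0
  one$area_km2[3] <- 100
  one$density[3] <- 7
  expect_equal(effective_area_occupied(one)$eao_km2, 100)

  # two equal cells at northing 0 and 100 with d = 1 and 3: COG = 75
  two <- data.frame(cell_id = 1:2, x_km = 0, y_km = c(0, 100),
                    area_km2 = 50, year = 1, density = c(1, 3))
  class(two) <- c("density_surface", "data.frame")
  expect_equal(center_of_gravity(two)$northing_km, 75)

  # doubling density doubles the index
  dbl <- surf; dbl$density <- 2 * dbl$density
  expect_equal(abundance_index(dbl)$index, 2 * idx$index)
})

test_that("EAO never exceeds the total modeled area (Cauchy-Schwarz)", {
  for (s in 1:20) {
    surf <- rand_surface(n_cells = 30, n_years = 1, seed = 100 + s)
    expect_lte(effective_area_occupied(surf)$eao_km2,
               sum(surf$area_km2) * (1 + 1e-12))
  }
})

test_that("Gaussian draw correction reproduces the lognormal closed form", {
  mu <- 1.2; sigma <- 0.6
  out <- gaussian_draw_correct(exp, mu, sigma^2, n_draws = 1e4,
                               seed = 8)
  expect_lt(abs(out$mean - exp(mu + sigma^2 / 2)) /
              exp(mu + sigma^2 / 2), 0.02)
  # plug-in exp(mu) is biased low; the correction moves the right way
  expect_gt(out$mean, exp(mu))
  # Monte-Carlo error of the mean shrinks like 1/sqrt(n)
  errs <- sapply(c(100, 10000), function(n) {
    reps <- sapply(1:30, function(r) {
      gaussian_draw_correct(exp, mu, sigma^2, n_draws = n,
                            seed = 1000 * r)$mean
    })
    sd(reps)
  })
  expect_gt(errs[1] / errs[2], 5)   # expect about a factor of 10
})

test_that("bias correction: no random effects means no correction", {
  sc <- sim_scenario(n_years = 2, stations_per_year = 80,
                     fields = field_params(0, 0, 0, 0, 150),
                     n_knots = 5, seed = 21)
  s <- simulate_survey(sc)
  cfg <- delta_model_config(fields = c(FALSE, FALSE, FALSE, FALSE),
                            n_knots = 5)
  fit <- fit_delta_model(s$stations, cfg, mesh = s$mesh)
  bc <- bias_correct_indices(fit, n_draws = 50, seed = 1)
  plug <- annual_indices(fit)
  expect_false(any(bc$bias_corrected))
  expect_equal(bc$index, plug$index)
})

test_that("bias-corrected index exceeds plug-in under log-scale convexity", {
  fit <- desk_fit()
  bc <- cached("desk_bc", bias_correct_indices(fit, n_draws = 200,
                                               seed = 3))
  plug <- annual_indices(fit)
  expect_true(all(bc$bias_corrected))
  expect_true(all(bc$index > plug$index))
  expect_true(all(bc$se_index > 0))
  # COG stays inside the grid bounding box
  g <- fit$mesh$grid
  expect_true(all(bc$northing_km > min(g$y_km) &
                    bc$northing_km < max(g$y_km)))
})

test_that("northward-shifting truth yields increasing estimated COG", {
  rhos <- sapply(1:3, function(r) {
    sc <- sim_scenario(n_years = 6, stations_per_year = 90,
                       n_knots = 15, cog_shift = 0.8,
                       fields = field_params(0.5, 0.3, 0.3, 0.2, 150),
                       seed = 400 + r)
    s <- simulate_survey(sc)
    fit <- fit_delta_model(s$stations,
                           delta_model_config(n_knots = 15,
                                              grid_spacing_km = 25),
                           mesh = s$mesh)
    cog <- center_of_gravity(predict_density(fit))
    cor(cog$year, cog$northing_km, method = "spearman")
  })
  expect_gt(mean(rhos), 0.8)
})
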