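# Shared fixtures, built in code.  Expensive fits are cached for the
# duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small deterministic station table on a unit-ish domain
square_stations <- function(n_side = 6, n_years = 2, spacing = 50,
                            catch = NULL, seed = 99) {
  pts <- expand.grid(x = (seq_len(n_side) - 0.5) * spacing,
                     y = (seq_len(n_side) - 0.5) * spacing)
  st <- do.call(rbind, lapply(seq_len(n_years), function(t) {
    data.frame(station_id = sprintf("S%03d", seq_len(nrow(pts))),
               year = t, easting_km = pts$x, northing_km = pts$y,
               area_swept = 0.15)
  }))
  if (is.null(catch)) {
    st$catch <- with_test_seed(seed, rgamma(nrow(st), 2, 0.5) *
                                 rbinom(nrow(st), 1, 0.7))
  } else {
    st$catch <- catch
  }
  st
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# default desk-scale simulated survey + base fit, shared across files
desk_sim <- function() {
  cached("desk_sim", simulate_survey(sim_scenario(seed = 11)))
}

desk_fit <- function() {
  cached("desk_fit", {
    s <- desk_sim()
    fit_delta_model(s$stations,
                    delta_model_config(n_knots = 25,
                                       grid_spacing_km = 20),
                    mesh = s$mesh)
  })
}

# independent Matern correlation (direct special-function evaluation)
matern_direct <- function(D, range_km) {
  xstar <- uniroot(function(x) x * besselK(x, 1) - 0.1, c(0.5, 8),
                   tol = 1e-12)$root
  kd <- xstar / range_km * D
  C <- ifelse(kd > 0, kd * besselK(kd, 1), 1)
  diag(C) <- 1 + 1e-8
  C
}

# independent observation log-likelihood of the Poisson-link delta-gamma
# model, written from the closed forms (used as the quadrature oracle)
obs_loglik_manual <- function(catch, p1, p2, area, cv) {
  m <- area * exp(p1)
  r1 <- 1 - exp(-m)
  r2 <- m / r1 * exp(p2)
  ifelse(catch == 0, -m,
         log(r1) + dgamma(catch, shape = 1 / cv^2, scale = r2 * cv^2,
                          log = TRUE))
}

# Adaptive Gauss-Hermite integration of exp(-jnll(u)) over d = 1 or 2
# random effects: nodes are centered at the mode of the integrand (found
# independently with optim) and scaled by its Hessian, then the tensor
# quadrature sum is accumulated in log space.
gh_adaptive_logml <- function(jnll, d, n_nodes = 40, start = rep(0, d)) {
  opt <- optim(start, jnll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  H <- numDeriv::hessian(jnll, opt$par)
  A <- t(chol(solve(H)))                 # u = mode + sqrt(2) A x
  gh <- statmod::gauss.quad(n_nodes, kind = "hermite")
  if (d == 1) {
    xg <- matrix(gh$nodes, ncol = 1)
    lw <- log(gh$weights) + gh$nodes^2
  } else {
    g <- expand.grid(i = seq_len(n_nodes), j = seq_len(n_nodes))
    xg <- cbind(gh$nodes[g$i], gh$nodes[g$j])
    lw <- log(gh$weights[g$i]) + log(gh$weights[g$j]) +
      rowSums(xg^2)
  }
  vals <- vapply(seq_len(nrow(xg)), function(k) {
    -jnll(opt$par + sqrt(2) * drop(A %*% xg[k, ]))
  }, numeric(1))
  s <- lw + vals
  m <- max(s)
  d * 0.5 * log(2) + sum(log(diag(A))) + m + log(sum(exp(s - m)))
}

# toy single-year dataset with d knot random effects on p1, catches
# drawn from the model itself; n is chosen large enough that the Laplace
# approximation error is negligible against the quadrature oracle
laplace_toy <- function(n, d, seed, sd_o = 0.5, a1 = 0.8, a2 = 0.1,
                        cv = 0.8, range_km = 120) {
  set.seed(seed)
  st <- data.frame(station_id = sprintf("S%05d", 1:n), year = 1,
                   easting_km = runif(n, 0, 300),
                   northing_km = runif(n, 0, 300),
                   area_swept = 0.15, catch = 0)
  mesh <- build_mesh(st, n_knots = d, buffer_km = 400, seed = 1)
  C <- if (d == 1) matrix(1 + 1e-8, 1, 1) else
    matern_direct(mesh$distances, range_km)
  u <- drop(t(chol(sd_o^2 * C)) %*% rnorm(d))
  m <- st$area_swept * exp(a1 + u[mesh$station_to_knot])
  r1 <- 1 - exp(-m); r2 <- m / r1 * exp(a2)
  st$catch <- rbinom(n, 1, r1) * rgamma(n, 1 / cv^2, scale = r2 * cv^2)
  list(st = st, mesh = mesh, C = C, sd_o = sd_o, a1 = a1, a2 = a2,
       cv = cv, range_km = range_km)
}

# joint negative log-likelihood (prior + observation) for a toy model
# with random effects on p1 only, written independently of the package
toy_jnll <- function(catch, p1_fixed, p2, area, cv, knot_idx, Sigma) {
  Lc <- chol(Sigma)
  ldet <- 2 * sum(log(diag(Lc)))
  d <- nrow(Sigma)
  function(u) {
    q <- sum(backsolve(Lc, u, transpose = TRUE)^2)
    prior <- 0.5 * (d * log(2 * pi) + ldet + q)
    prior - sum(obs_loglik_manual(catch, p1_fixed + u[knot_idx], p2,
                                  area, cv))
  }
}
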