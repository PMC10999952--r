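#' Define a synthetic trawl-survey scenario
#'
#' Describes the study conditions emulated by the generator: an unbalanced
#' multi-year station layout on a Bering-shelf-sized domain, warm/cool
#' temperature stanzas with a north-south gradient, spatial and
#' spatio-temporal log-density fields, optional covariate effects on the
#' linear predictors (a linear slope or a dome with a stated peak), and
#' zero-inflated positive-skewed catches from the Poisson-link delta-gamma
#' observation model.
#'
#' @param n_years Number of survey years.
#' @param stations_per_year Stations per year (scalar, or vector of length
#'   `n_years` for an unbalanced design).
#' @param extent_km Domain extent `c(east-west, north-south)` in km.
#' @param origin_km Lower-left corner `c(easting, northing)` in km (the
#'   defaults sit at Bering-shelf latitudes).
#' @param n_knots,buffer_km,grid_spacing_km Mesh settings for the truth
#'   fields and the extrapolation grid.
#' @param fields A [field_params()] object (the truth).
#' @param alpha1,alpha2 Optional fixed year-intercept vectors; generated
#'   as Gaussian series around `alpha1_mean`/`alpha2_mean` when `NULL`.
#' @param alpha1_mean,alpha1_sd,alpha2_mean,alpha2_sd Intercept series
#'   hyper-parameters (log scale).
#' @param obs_cv CV of the positive-catch gamma distribution; `0` yields
#'   noiseless expected catches `a exp(p1 + p2)`.
#' @param area_swept_range Uniform range of per-tow effort (km^2);
#'   defaults to a 55 m net opening towed 1.8-3.6 km.
#' @param stanza Character vector (`"warm"`/`"cool"`) per year; the
#'   default emulates a warm-cool-warm sequence.
#' @param temp_warm_mean,temp_cool_mean,temp_year_sd Stanza-level annual
#'   mean temperatures at 20 m (deg C) and their year-to-year spread.
#' @param temp_ns_gradient Deg C per km of northing (negative = cooler
#'   north).
#' @param temp_st_sd SD (deg C) of a smooth knot-level spatio-temporal
#'   temperature anomaly (what makes temperature able to explain
#'   spatio-temporal density structure, as sea temperature does).
#' @param temp_station_sd Station-level temperature noise SD (deg C).
#' @param covariate_effect `NULL`, or a list describing the truth effect:
#'   `list(name, type = "linear", slope1, slope2)` acting on a standard
#'   normal covariate, or `list(name = "temp20", type = "dome", peak,
#'   curvature, curvature2)` acting on temperature (log-density drops
#'   quadratically away from `peak`).
#' @param extra_covariates Names of additional iid standard-normal
#'   covariates attached to stations and grid (no effect on density).
#' @param cog_shift Strength of a year-by-northing tilt of log density
#'   (0 = stationary distribution; positive values move the center of
#'   gravity north over the study period).
#' @param seed Mandatory integer seed; the whole scenario is reproducible
#'   from it.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_years = 8, stations_per_year = 120,
                         extent_km = c(600, 400),
                         origin_km = c(300, 6300),
                         n_knots = 25, buffer_km = 25,
                         grid_spacing_km = 20,
                         fields = field_params(),
                         alpha1 = NULL, alpha2 = NULL,
                         alpha1_mean = 1.8, alpha1_sd = 0.4,
                         alpha2_mean = 0, alpha2_sd = 0.2,
                         obs_cv = 0.8,
                         area_swept_range = c(0.1, 0.2),
                         stanza = NULL,
                         temp_warm_mean = 11.3, temp_cool_mean = 8.8,
                         temp_year_sd = 0.5,
                         temp_ns_gradient = -0.004,
                         temp_st_sd = 0.8,
                         temp_station_sd = 0.5,
                         covariate_effect = NULL,
                         extra_covariates = character(),
                         cog_shift = 0,
                         seed = 1) {
  if (is.null(stanza)) {
    # warm-cool-warm sequence in roughly 3:3:2 proportion
    cuts <- round(n_years * c(3, 6) / 8)
    stanza <- c(rep("warm", cuts[1]), rep("cool", cuts[2] - cuts[1]),
                rep("warm", n_years - cuts[2]))
  }
  stopifnot(length(stanza) == n_years,
            all(stanza %in% c("warm", "cool")),
            obs_cv >= 0, n_years >= 1)
  stations_per_year <- rep_len(stations_per_year, n_years)
  env <- as.list(environment())
  env$cuts <- NULL
  structure(env, class = "sim_scenario")
}

# truth covariate contribution to (p1, p2) given covariate values
truth_effect <- function(effect, values) {
  if (is.null(effect)) return(list(p1 = 0, p2 = 0))
  if (effect$type == "linear") {
    list(p1 = (effect$slope1 %||% 0) * values,
         p2 = (effect$slope2 %||% 0) * values)
  } else if (effect$type == "dome") {
    dev2 <- (values - effect$peak)^2
    list(p1 = -(effect$curvature %||% 0.03) * dev2,
         p2 = -(effect$curvature2 %||% 0) * dev2)
  } else stop("unknown covariate effect type: ", effect$type)
}

#' Simulate a complete synthetic trawl survey
#'
#' Lays out jittered station grids with random dropouts per year, builds
#' the knot mesh, draws the truth random fields, constructs station and
#' grid covariates (temperature with stanza structure plus any extra
#' standard-normal covariates), assembles the linear predictors, and draws
#' catches from the Poisson-link delta-gamma observation model.  The truth
#' density surface on the extrapolation grid and the truth annual indices
#' derived from it are returned alongside the observable station table.
#'
#' @param scenario A [sim_scenario()].
#' @return List with `stations` (observable survey table), `mesh`, and
#'   `truth` (fields, intercepts, density `surface`, `indices`, and the
#'   scenario).
#' @export
simulate_survey <- function(scenario) {
  sc <- scenario
  stopifnot(inherits(sc, "sim_scenario"))
  if (any(sc$extent_km <= 0)) stop("degenerate domain extent")
  with_seed(sc$seed, {
    years <- seq_len(sc$n_years)
    # --- station layout: jittered lattice with dropouts, per year
    st <- list()
    for (t in years) {
      n_t <- sc$stations_per_year[t]
      n_side <- ceiling(sqrt(n_t * 1.3))
      sp_x <- sc$extent_km[1] / n_side
      sp_y <- sc$extent_km[2] / n_side
      gx <- sc$origin_km[1] + (seq_len(n_side) - 0.5) * sp_x
      gy <- sc$origin_km[2] + (seq_len(n_side) - 0.5) * sp_y
      pts <- expand.grid(x = gx, y = gy)
      pts$x <- pts$x + runif(nrow(pts), -0.3 * sp_x, 0.3 * sp_x)
      pts$y <- pts$y + runif(nrow(pts), -0.3 * sp_y, 0.3 * sp_y)
      keep <- sort(sample.int(nrow(pts), n_t))
      st[[t]] <- data.frame(
        station_id = sprintf("Y%02d_S%03d", t, seq_len(n_t)),
        year = t,
        easting_km = pts$x[keep], northing_km = pts$y[keep],
        area_swept = runif(n_t, sc$area_swept_range[1],
                           sc$area_swept_range[2]))
    }
    stations <- do.call(rbind, st)
    stations$catch <- 0   # placeholder until the observation draw below

    mesh <- build_mesh(stations, n_knots = sc$n_knots,
                       buffer_km = sc$buffer_km,
                       grid_spacing_km = sc$grid_spacing_km,
                       seed = sc$seed)
    fields <- simulate_fields(mesh, sc$fields, sc$n_years,
                              seed = sc$seed + 1)

    alpha1 <- sc$alpha1 %||% rnorm(sc$n_years, sc$alpha1_mean,
                                   sc$alpha1_sd)
    alpha2 <- sc$alpha2 %||% rnorm(sc$n_years, sc$alpha2_mean,
                                   sc$alpha2_sd)

    # --- temperature: stanza-level annual means + N-S gradient + a
    # smooth spatio-temporal anomaly at knots + station noise
    year_mean <- ifelse(sc$stanza == "warm", sc$temp_warm_mean,
                        sc$temp_cool_mean) +
      rnorm(sc$n_years, 0, sc$temp_year_sd)
    cy <- sc$origin_km[2] + sc$extent_km[2] / 2
    temp_anom <- simulate_fields(
      mesh, field_params(0, 0, sc$temp_st_sd, 0,
                         sc$fields$range_km),
      sc$n_years, seed = sc$seed + 2)$eps1
    temp_at <- function(y_km, knot, t) {
      year_mean[t] + sc$temp_ns_gradient * (y_km - cy) +
        temp_anom[cbind(knot, t)]
    }
    stations$temp20 <- temp_at(stations$northing_km,
                               mesh$station_to_knot, stations$year) +
      rnorm(nrow(stations), 0, sc$temp_station_sd)

    g <- mesh$grid
    grid_cov <- data.frame(cell_id = rep(g$cell_id, sc$n_years),
                           year = rep(years, each = nrow(g)))
    grid_cov$temp20 <- temp_at(rep(g$y_km, sc$n_years),
                               rep(g$knot_id, sc$n_years),
                               grid_cov$year)

    for (nm in unique(c(sc$extra_covariates,
                        if (!is.null(sc$covariate_effect) &&
                            sc$covariate_effect$type == "linear")
                          sc$covariate_effect$name))) {
      if (is.null(nm) || nm == "temp20") next
      stations[[nm]] <- rnorm(nrow(stations))
      grid_cov[[nm]] <- rnorm(nrow(grid_cov))
    }

    # --- linear predictors at stations
    t_sc <- if (sc$n_years > 1) {
      2 * (stations$year - 1) / (sc$n_years - 1) - 1
    } else 0
    y_std <- (stations$northing_km - cy) / (sc$extent_km[2] / 4)
    si <- mesh$station_to_knot
    eff_st <- if (is.null(sc$covariate_effect)) list(p1 = 0, p2 = 0) else
      truth_effect(sc$covariate_effect,
                   stations[[sc$covariate_effect$name]])
    p1 <- alpha1[stations$year] + fields$omega1[si] +
      fields$eps1[cbind(si, stations$year)] + eff_st$p1 +
      sc$cog_shift * t_sc * y_std
    p2 <- alpha2[stations$year] + fields$omega2[si] +
      fields$eps2[cbind(si, stations$year)] + eff_st$p2

    lk <- poisson_link(p1, p2, stations$area_swept)
    if (sc$obs_cv == 0) {
      stations$catch <- stations$area_swept * exp(p1 + p2)
    } else {
      enc <- rbinom(nrow(stations), 1, lk$r1)
      pos <- rgamma(nrow(stations), shape = 1 / sc$obs_cv^2,
                    scale = lk$r2 * sc$obs_cv^2)
      stations$catch <- ifelse(enc == 1, pos, 0)
    }

    # --- truth surface on the grid
    ct <- rep(g$knot_id, sc$n_years)
    gt_sc <- if (sc$n_years > 1) {
      2 * (grid_cov$year - 1) / (sc$n_years - 1) - 1
    } else 0
    gy_std <- (rep(g$y_km, sc$n_years) - cy) / (sc$extent_km[2] / 4)
    eff_g <- if (is.null(sc$covariate_effect)) list(p1 = 0, p2 = 0) else
      truth_effect(sc$covariate_effect,
                   grid_cov[[sc$covariate_effect$name]])
    gp1 <- alpha1[grid_cov$year] + fields$omega1[ct] +
      fields$eps1[cbind(ct, grid_cov$year)] + eff_g$p1 +
      sc$cog_shift * gt_sc * gy_std
    gp2 <- alpha2[grid_cov$year] + fields$omega2[ct] +
      fields$eps2[cbind(ct, grid_cov$year)] + eff_g$p2
    glk <- poisson_link(gp1, gp2, rep(1, length(gp1)))
    surface <- data.frame(cell_id = grid_cov$cell_id,
                          x_km = rep(g$x_km, sc$n_years),
                          y_km = rep(g$y_km, sc$n_years),
                          area_km2 = rep(g$area_km2, sc$n_years),
                          year = grid_cov$year,
                          density = glk$r1 * glk$r2)
    class(surface) <- c("density_surface", "data.frame")

    indices <- merge(merge(abundance_index(surface),
                           center_of_gravity(surface), by = "year"),
                     effective_area_occupied(surface), by = "year")

    list(stations = stations, mesh = mesh, grid_covariates = grid_cov,
         truth = list(fields = fields, alpha1 = alpha1, alpha2 = alpha2,
                      year_mean_temp = year_mean, surface = surface,
                      indices = indices, scenario = sc))
  })
}

#' Simulate pooled stomach-content records
#'
#' Per-station prey-weight compositions are Dirichlet draws whose expected
#' proportions depend on the year's stanza: warm years up-weight age-0
#' pollock, cool years up-weight euphausiids (the observed contrast in
#' juvenile sockeye diets).  Predator (pooled) weights are lognormal.
#'
#' @param scenario A [sim_scenario()] (supplies years, stanzas, seed).
#' @param categories Prey category names; must include the first two
#'   (`pollock`-like and `euphausiid`-like) for the stanza contrast.
#' @param stations_per_year Diet stations per year.
#' @param contrast Stanza contrast parameter `>= 0`; `0` removes any
#'   warm/cool difference in expected proportions.
#' @param seed Seed (defaults to `scenario$seed + 1000`).
#' @return data.frame `station_id, year, n_stomachs, predator_weight` plus
#'   one prey-weight column (g) per category.
#' @export
simulate_diet <- function(scenario,
                          categories = c("age0_pollock", "euphausiids",
                                         "other_fishes", "amphipods",
                                         "calanus", "pteropods"),
                          stations_per_year = 30, contrast = 2,
                          seed = scenario$seed + 1000) {
  if (!length(categories)) stop("categories must be non-empty")
  k <- length(categories)
  base_alpha <- c(1.5, 1.5, 1.2, 0.8, 0.6, 0.4)[seq_len(min(k, 6))]
  base_alpha <- c(base_alpha, rep(0.4, max(0, k - 6)))
  with_seed(seed, {
    rows <- list()
    for (t in seq_len(scenario$n_years)) {
      a <- base_alpha
      if (k >= 2) {
        if (scenario$stanza[t] == "warm") a[1] <- a[1] * (1 + contrast)
        else a[2] <- a[2] * (1 + contrast)
      }
      for (s in seq_len(stations_per_year)) {
        gam <- rgamma(k, shape = a, rate = 1)
        props <- if (k == 1) 1 else gam / sum(gam)
        pred_w <- rlnorm(1, log(1000), 0.35)
        total_prey <- pred_w * rlnorm(1, log(0.012), 0.4)
        w <- total_prey * props
        rows[[length(rows) + 1L]] <- data.frame(
          station_id = sprintf("D%02d_%03d", t, s), year = t,
          n_stomachs = 5L + stats::rpois(1, 4),
          predator_weight = pred_w,
          t(setNames(w, categories)))
      }
    }
    do.call(rbind, rows)
  })
}
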