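test_that("coordinate projection follows the km-from-180/Equator convention", {
  expect_equal(unlist(project_coordinates(-180, 0)),
               c(easting_km = 0, northing_km = 0))
  expect_equal(project_coordinates(-180, 60)$northing_km, 6671.7)
  # cos(60 deg) = 1/2 exactly: easting = 111.195 * 0.5 * 10
  p <- project_coordinates(-170, 60)
  expect_equal(p$easting_km, 555.975)
  expect_equal(p$northing_km, 6671.7)
  # monotone in both arguments within a latitude band
  lons <- seq(-179, -159, by = 2)
  expect_true(all(diff(project_coordinates(lons, rep(57, 11))$easting_km) > 0))
  lats <- seq(54, 60, by = 0.5)
  expect_true(all(diff(project_coordinates(rep(-170, 13), lats)$northing_km) > 0))
  expect_error(project_coordinates(NA, 60), "non-finite")
  expect_error(project_coordinates(-170, 95), "latitude")
})

test_that("mesh: degenerate knot counts and determinism", {
  st <- square_stations(n_side = 2, n_years = 1, spacing = 100)
  # k = n: knots are the stations themselves, each mapping to itself
  m <- build_mesh(st, n_knots = 4, buffer_km = 30, grid_spacing_km = 20,
                  seed = 1)
  xy <- cbind(st$easting_km, st$northing_km)
  reord <- m$station_to_knot
  expect_equal(unname(m$knots[reord, ]), unname(xy), tolerance = 1e-12)
  expect_equal(sort(reord), 1:4)
  # k = 1: centroid
  m1 <- build_mesh(st, n_knots = 1, buffer_km = 80, grid_spacing_km = 20,
                   seed = 1)
  expect_equal(unname(drop(m1$knots)), unname(colMeans(xy)),
               tolerance = 1e-12)
  # determinism under a fixed seed
  st2 <- with_test_seed(5, data.frame(
    station_id = sprintf("S%03d", 1:100), year = 1,
    easting_km = runif(100, 0, 500), northing_km = runif(100, 0, 500),
    area_swept = 0.15, catch = 1))
  ma <- build_mesh(st2, n_knots = 10, seed = 42)
  mb <- build_mesh(st2, n_knots = 10, seed = 42)
  expect_identical(ma$knots, mb$knots)
  expect_identical(ma$grid, mb$grid)
})

test_that("station-to-knot assignment is the brute-force arg-min", {
  st <- with_test_seed(7, data.frame(
    station_id = sprintf("S%03d", 1:150), year = 1,
    easting_km = runif(150, 0, 400), northing_km = runif(150, 0, 400),
    area_swept = 0.15, catch = 1))
  # buffer chosen to exceed the within-cluster radius of this layout so
  # the retained grid covers the stations
  m <- build_mesh(st, n_knots = 12, buffer_km = 80, seed = 3)
  xy <- cbind(st$easting_km, st$northing_km)
  brute <- vapply(seq_len(nrow(xy)), function(i) {
    which.min(sqrt((m$knots[, 1] - xy[i, 1])^2 +
                     (m$knots[, 2] - xy[i, 2])^2))
  }, integer(1))
  expect_equal(m$station_to_knot, brute)
  # grid clipping: every retained cell within buffer of some knot
  dmin <- apply(m$grid[, c("x_km", "y_km")], 1, function(p) {
    min(sqrt((m$knots[, 1] - p[1])^2 + (m$knots[, 2] - p[2])^2))
  })
  expect_true(all(dmin <= m$buffer_km))
  # stations lie inside the retained grid's bounding region
  expect_true(all(st$easting_km >= min(m$grid$x_km) - m$grid_spacing_km &
                    st$easting_km <= max(m$grid$x_km) + m$grid_spacing_km))
  expect_equal(sum(m$grid$area_km2),
               nrow(m$grid) * m$grid_spacing_km^2)
})

test_that("covariate gap-filling: exact, midpoint, and barycentric cases", {
  # coincident station gets the observed value; collinear midpoint
  # averages its neighbours
  st <- data.frame(station_id = sprintf("S%d", 1:4), year = 1,
                   easting_km = c(0, 100, 50, 0),
                   northing_km = c(0, 0, 0, 0),
                   area_swept = 0.15, catch = 1,
                   temp = c(8, 10, NA, NA))
  out <- fill_missing_covariate(st, "temp")
  expect_equal(out$temp[3], 9)     # midpoint of 8 and 10
  expect_equal(out$temp[4], 8)     # coincident with station 1
  expect_identical(out$temp_filled, c(FALSE, FALSE, TRUE, TRUE))

  # interior point of a triangle with equal barycentric weights
  tri <- data.frame(station_id = sprintf("S%d", 1:4), year = 1,
                    easting_km = c(0, 90, 0, 30),
                    northing_km = c(0, 0, 90, 30),
                    area_swept = 0.15, catch = 1,
                    temp = c(6, 9, 12, NA))
  out2 <- fill_missing_covariate(tri, "temp")
  expect_equal(out2$temp[4], (6 + 9 + 12) / 3, tolerance = 1e-10)

  # outside the hull: nearest neighbour
  far <- rbind(tri[1:3, ], data.frame(station_id = "S5", year = 1,
                                      easting_km = 200, northing_km = 0,
                                      area_swept = 0.15, catch = 1,
                                      temp = NA))
  expect_equal(fill_missing_covariate(far, "temp")$temp[4], 9)

  # a year with no observations at all errors with the year named
  bad <- tri
  bad$temp <- NA_real_
  expect_error(fill_missing_covariate(bad, "temp"), "year 1")
})
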