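#' Project geographic coordinates to survey-plane kilometres
#'
#' Converts longitude/latitude to the planar "km from 180 / km from Equator"
#' convention used for reporting centers of gravity: northing is kilometres
#' north of the Equator and easting kilometres east of the 180th meridian,
#' with the east-west scale shrunk by `cos(lat)`.  One degree of latitude is
#' taken as 111.195 km (the mean-Earth-radius arc length).
#'
#' @param lon Longitude in decimal degrees, in `[-180, 180]` (western
#'   hemisphere negative).
#' @param lat Latitude in decimal degrees, strictly between -90 and 90.
#' @return A data.frame with columns `easting_km` and `northing_km`.
#' @examples
#' project_coordinates(-170, 60)   # 555.975 km east of 180, 6671.7 km north
#' @export
project_coordinates <- function(lon, lat) {
  bad <- !is.finite(lon) | !is.finite(lat)
  if (any(bad)) {
    stop("non-finite lon/lat at record(s): ",
         paste(which(bad), collapse = ", "))
  }
  if (any(lon < -180 | lon > 180)) {
    stop("longitude outside [-180, 180] at record(s): ",
         paste(which(lon < -180 | lon > 180), collapse = ", "))
  }
  if (any(lat <= -90 | lat >= 90)) {
    stop("latitude outside (-90, 90) at record(s): ",
         paste(which(lat <= -90 | lat >= 90), collapse = ", "))
  }
  km_per_deg <- 111.195
  data.frame(
    easting_km  = km_per_deg * cos(lat * pi / 180) * (lon + 180),
    northing_km = km_per_deg * lat
  )
}

#' Read and validate a station table
#'
#' Reads a CSV of station-tow records, checks the survey-table invariants
#' (positive area swept, non-negative catch, no duplicated station-year,
#' finite coordinates), and derives planar coordinates when only lon/lat are
#' present.
#'
#' @param path CSV file with headers `station_id, year, lon, lat,
#'   area_swept, catch` (or `easting_km`/`northing_km` in place of lon/lat)
#'   plus any covariate columns; missing covariate values as empty cells.
#' @return A validated station data.frame with `easting_km`/`northing_km`.
#' @export
read_stations <- function(path) {
  st <- read.csv(path, stringsAsFactors = FALSE)
  validate_stations(st)
}

#' @rdname read_stations
#' @param stations A station data.frame to validate in place of a file.
#' @export
validate_stations <- function(stations) {
  need <- c("station_id", "year", "area_swept", "catch")
  miss <- setdiff(need, names(stations))
  if (length(miss)) stop("station table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(c("easting_km", "northing_km") %in% names(stations))) {
    if (!all(c("lon", "lat") %in% names(stations))) {
      stop("station table needs either easting_km/northing_km or lon/lat")
    }
    stations <- cbind(stations,
                      project_coordinates(stations$lon, stations$lat))
  }
  if (nrow(stations) == 0L) stop("empty station table")
  if (any(!is.finite(stations$easting_km)) ||
      any(!is.finite(stations$northing_km))) {
    stop("non-finite station coordinates")
  }
  if (any(stations$area_swept <= 0)) stop("area_swept must be > 0")
  if (any(stations$catch < 0)) stop("catch must be >= 0")
  dup <- duplicated(stations[c("station_id", "year")])
  if (any(dup)) {
    stop("duplicated (station_id, year): ",
         paste(head(stations$station_id[dup]), collapse = ", "))
  }
  stations
}

#' Build a knot mesh and extrapolation grid from station locations
#'
#' Knot locations are the k-means centers of the pooled station coordinates
#' across all years (10 restarts, best within-cluster sum of squares).  The
#' extrapolation grid is a regular lattice clipped to cells whose center
#' lies within `buffer_km` of at least one knot; each cell and each station
#' is assigned to its nearest knot.
#'
#' @param stations Validated station data.frame (see [validate_stations()]).
#' @param n_knots Number of knots; must not exceed the number of distinct
#'   station locations.
#' @param buffer_km Clipping radius around each knot (km).
#' @param grid_spacing_km Lattice spacing; each retained cell has area
#'   `grid_spacing_km^2`.
#' @param seed Integer seed controlling the k-means restarts.
#' @return An object of class `survey_mesh`: `knots` (matrix, km),
#'   `station_to_knot`, `grid` (data.frame `cell_id, x_km, y_km, area_km2,
#'   knot_id`), `buffer_km`, `grid_spacing_km`, `distances` (knot-to-knot
#'   km).
#' @export
build_mesh <- function(stations, n_knots = 50, buffer_km = 25,
                       grid_spacing_km = 10, seed = 1) {
  stations <- validate_stations(stations)
  xy <- cbind(stations$easting_km, stations$northing_km)
  n_distinct <- nrow(unique(xy))
  if (n_knots < 1) stop("n_knots must be >= 1")
  if (n_knots > n_distinct) {
    stop("n_knots (", n_knots, ") exceeds distinct station locations (",
         n_distinct, ")")
  }
  if (buffer_km <= 0) stop("buffer_km must be > 0")
  knots <- with_seed(seed, {
    if (n_knots == n_distinct) {
      unique(xy)
    } else {
      kmeans(xy, centers = n_knots, nstart = 10, iter.max = 100)$centers
    }
  })
  knots <- unname(as.matrix(knots))
  colnames(knots) <- c("x_km", "y_km")

  station_to_knot <- nearest_index(xy, knots)

  gx <- seq(floor((min(knots[, 1]) - buffer_km) / grid_spacing_km),
            ceiling((max(knots[, 1]) + buffer_km) / grid_spacing_km)) *
    grid_spacing_km + grid_spacing_km / 2
  gy <- seq(floor((min(knots[, 2]) - buffer_km) / grid_spacing_km),
            ceiling((max(knots[, 2]) + buffer_km) / grid_spacing_km)) *
    grid_spacing_km + grid_spacing_km / 2
  cells <- as.matrix(expand.grid(x_km = gx, y_km = gy))
  d2 <- cross_dist2(cells, knots)
  mind <- sqrt(apply(d2, 1, min))
  keep <- mind <= buffer_km
  cells <- cells[keep, , drop = FALSE]
  cell_to_knot <- apply(d2[keep, , drop = FALSE], 1, which.min)

  structure(list(
    knots = knots,
    station_to_knot = station_to_knot,
    grid = data.frame(
      cell_id = seq_len(nrow(cells)),
      x_km = cells[, 1], y_km = cells[, 2],
      area_km2 = grid_spacing_km^2,
      knot_id = cell_to_knot
    ),
    buffer_km = buffer_km,
    grid_spacing_km = grid_spacing_km,
    distances = as.matrix(dist(knots)),
    seed = seed
  ), class = "survey_mesh")
}

#' @export
print.survey_mesh <- function(x, ...) {
  cat("survey_mesh:", nrow(x$knots), "knots,", nrow(x$grid),
      "grid cells of", x$grid$area_km2[1], "km^2 (total",
      format(sum(x$grid$area_km2), big.mark = ","), "km^2), buffer",
      x$buffer_km, "km\n")
  invisible(x)
}

#' Assign new locations to their nearest knot
#'
#' @param mesh A `survey_mesh`.
#' @param xy Two-column matrix of easting/northing (km).
#' @return Integer vector of knot indices.
#' @export
assign_to_knot <- function(mesh, xy) {
  nearest_index(as.matrix(xy), mesh$knots)
}

#' Write mesh knots and grid to CSV
#'
#' @param mesh A `survey_mesh`.
#' @param knots_path,grid_path Output CSV paths.
#' @export
write_mesh_csv <- function(mesh, knots_path, grid_path) {
  write.csv(data.frame(knot_id = seq_len(nrow(mesh$knots)),
                       x_km = mesh$knots[, 1], y_km = mesh$knots[, 2]),
            knots_path, row.names = FALSE)
  write.csv(mesh$grid, grid_path, row.names = FALSE)
  invisible(mesh)
}

#' Fill missing covariate values by within-year planar interpolation
#'
#' Missing values are replaced year by year: a local linear (barycentric)
#' interpolant through the three nearest non-collinear observed stations is
#' evaluated at the missing location when it lies inside the convex hull of
#' that year's observations; outside the hull the nearest observed value is
#' carried over.  A station coincident with an observed one receives that
#' station's value exactly.  The provenance of every filled value is
#' recorded in a logical column `<name>_filled`.
#'
#' @param stations Validated station data.frame.
#' @param covariate_name Column to fill.
#' @return The station table with missing values filled and a
#'   `<name>_filled` flag column.
#' @export
fill_missing_covariate <- function(stations, covariate_name) {
  stations <- validate_stations(stations)
  if (!covariate_name %in% names(stations)) {
    stop("no covariate column named '", covariate_name, "'")
  }
  v <- stations[[covariate_name]]
  filled <- rep(FALSE, nrow(stations))
  for (yr in unique(stations$year)) {
    idx <- which(stations$year == yr)
    obs <- idx[!is.na(v[idx])]
    mis <- idx[is.na(v[idx])]
    if (!length(mis)) next
    if (!length(obs)) stop("all '", covariate_name,
                           "' values missing in year ", yr)
    P <- cbind(stations$easting_km[obs], stations$northing_km[obs])
    z <- v[obs]
    for (m in mis) {
      q <- c(stations$easting_km[m], stations$northing_km[m])
      v[m] <- interp_planar(P, z, q)
      filled[m] <- TRUE
    }
  }
  stations[[covariate_name]] <- v
  stations[[paste0(covariate_name, "_filled")]] <- filled
  stations
}

## --- internal geometry helpers ------------------------------------------

# squared distances between rows of a (n x 2) and b (m x 2)
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
}

nearest_index <- function(a, b) {
  apply(cross_dist2(a, b), 1, which.min)
}

# evaluate RNG-dependent code without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# point-in-convex-hull test (hull given as chull indices of P, CCW or CW)
in_hull <- function(P, q, tol = 1e-9) {
  h <- grDevices::chull(P)
  H <- P[h, , drop = FALSE]
  n <- nrow(H)
  if (n < 3) return(FALSE)
  sgn <- 0
  for (k in seq_len(n)) {
    a <- H[k, ]; b <- H[if (k == n) 1 else k + 1, ]
    cr <- (b[1] - a[1]) * (q[2] - a[2]) - (b[2] - a[2]) * (q[1] - a[1])
    if (abs(cr) < tol) next
    s <- sign(cr)
    if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
  }
  TRUE
}

# linear interpolation at point q from observed planar points P with values z:
# plane through the 3 nearest non-collinear points inside the hull, nearest
# neighbour outside; exact match at zero distance; 1-D linear fallback when
# all observations are collinear.
interp_planar <- function(P, z, q) {
  d2 <- colSums((t(P) - q)^2)
  o <- order(d2)
  if (d2[o[1]] < 1e-12) return(z[o[1]])
  # collinear overall? check rank of centered coordinates
  Pc <- sweep(P, 2, colMeans(P))
  collinear <- nrow(P) < 3 || qr(Pc)$rank < 2
  if (collinear) {
    # project onto the principal direction and interpolate in 1-D
    dir <- if (nrow(P) == 1) c(1, 0) else {
      sv <- svd(Pc)
      sv$v[, 1]
    }
    s <- drop(P %*% dir)
    sq <- sum(q * dir)
    ord <- order(s)
    s <- s[ord]; zz <- z[ord]
    if (sq <= s[1]) return(zz[1])
    if (sq >= s[length(s)]) return(zz[length(zz)])
    j <- findInterval(sq, s)
    w <- (sq - s[j]) / (s[j + 1] - s[j])
    return((1 - w) * zz[j] + w * zz[j + 1])
  }
  if (!in_hull(P, q)) return(z[o[1]])
  # three nearest non-collinear points define the local plane
  tri <- o[1:2]
  for (k in o[-(1:2)]) {
    M <- cbind(P[c(tri, k), ], 1)
    if (abs(det(M)) > 1e-9) { tri <- c(tri, k); break }
  }
  if (length(tri) < 3) return(z[o[1]])
  A <- cbind(1, P[tri, , drop = FALSE])
  beta <- solve(A, z[tri])
  drop(c(1, q) %*% beta)
}
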