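#' Stomach content index for one pooled station sample
#'
#' `SCI = 10000 * prey weight / predator weight` per prey taxon, computed
#' from the pooled stomach contents of the fish sampled at a station.
#'
#' @param prey_weights Named vector of per-taxon prey weights (g), `>= 0`.
#' @param predator_weight Total pooled predator weight (g), `> 0`.
#' @return Named vector of per-taxon SCI values.
#' @export
station_sci <- function(prey_weights, predator_weight) {
  if (predator_weight <= 0) stop("predator_weight must be > 0")
  if (any(prey_weights < 0)) stop("prey weights must be >= 0")
  10000 * prey_weights / predator_weight
}

#' Annual diet summary from pooled stomach samples
#'
#' Computes per-station SCI values, optionally maps taxa to broader prey
#' categories, averages the SCI of each category over the stations of each
#' year (unweighted by default, as stations are the sampling unit), and
#' derives diet proportions as each category mean divided by the sum of
#' the category means (proportions sum to 1 per year).
#'
#' @param records data.frame with columns `station_id, year, n_stomachs,
#'   predator_weight` and one column of pooled prey weight (g) per taxon.
#' @param category_map Optional named character vector mapping taxon
#'   column names to category names (taxa sharing a category are summed).
#' @param weight_by_stomachs If `TRUE`, annual means are weighted by
#'   `n_stomachs`.
#' @return data.frame `year, category, mean_sci, proportion`; years whose
#'   SCI are all zero get `NA` proportions.
#' @export
annual_diet_summary <- function(records, category_map = NULL,
                                weight_by_stomachs = FALSE) {
  meta <- c("station_id", "year", "n_stomachs", "predator_weight")
  miss <- setdiff(meta, names(records))
  if (length(miss)) stop("diet table lacks column(s): ",
                         paste(miss, collapse = ", "))
  taxa <- setdiff(names(records), meta)
  if (!length(taxa)) stop("no prey taxon columns found")
  W <- as.matrix(records[, taxa, drop = FALSE])
  if (!is.null(category_map)) {
    cats <- unname(category_map[taxa])
    cats[is.na(cats)] <- taxa[is.na(cats)]
    W <- t(rowsum(t(W), group = cats))
  }
  sci <- sweep(W, 1, records$predator_weight, "/") * 10000
  out <- do.call(rbind, lapply(sort(unique(records$year)), function(yr) {
    r <- records$year == yr
    w <- if (weight_by_stomachs) records$n_stomachs[r] else
      rep(1, sum(r))
    ms <- colSums(sci[r, , drop = FALSE] * w) / sum(w)
    tot <- sum(ms)
    data.frame(year = yr, category = colnames(sci), mean_sci = ms,
               proportion = if (tot > 0) ms / tot else NA_real_,
               row.names = NULL)
  }))
  out
}

#' Integrate a volumetric density over the sampled water column
#'
#' Converts a mean volumetric density (number per m^3) to an areal density
#' (number per m^2) by multiplying by the sampled water-column height,
#' `depth - 10` m (nets are deployed to 10 m off bottom).
#'
#' @param density_per_m3 Mean volumetric density, `>= 0`.
#' @param depth_m Bottom depth in metres, `> 10`.
#' @return Areal density (number per m^2).
#' @export
water_column_integration <- function(density_per_m3, depth_m) {
  if (any(depth_m <= 10)) {
    stop("depth must exceed 10 m (net deployed 10 m off bottom)")
  }
  density_per_m3 * (depth_m - 10)
}
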