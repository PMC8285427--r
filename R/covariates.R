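#' Standardize a covariate series
#'
#' Centers to mean zero and scales to variance one (population variance,
#' divisor n). Directional covariates such as wind direction are scaled but
#' not centered (`center = FALSE`), preserving their sign convention.
#'
#' @param x numeric vector or matrix with positive variance.
#' @param center logical; centre before scaling (default TRUE).
#' @param name covariate name used in error messages.
#' @return standardized object with the same shape as `x`.
#' @export
standardize <- function(x, center = TRUE, name = deparse(substitute(x))) {
  v <- as.vector(x)
  if (any(!is.finite(v))) stop("non-finite values in covariate ", name)
  s <- pop_sd(v)
  if (s == 0) stop("zero variance in covariate ", name)
  out <- if (center) (x - mean(v)) / s else x / s
  out
}

#' Sum two pollutant series into one exposure variable
#'
#' Nitrogen dioxide and sulphur dioxide are combined by elementwise
#' summation before standardization (the ordering matters: summing first and
#' standardizing the sum is not the same as summing two standardized
#' series).
#'
#' @param no2,so2 aligned numeric vectors or matrices in the same units.
#' @return the elementwise sum, same shape as the inputs.
#' @export
combine_pollutants <- function(no2, so2) {
  if (!identical(dim(no2), dim(so2)) || length(no2) != length(so2)) {
    stop("misaligned pollutant series")
  }
  if (!is.null(names(no2)) && !is.null(names(so2)) &&
      !identical(names(no2), names(so2))) {
    stop("misaligned pollutant series (names differ)")
  }
  no2 + so2
}

#' Assign each region the series of its nearest measurement station
#'
#' Aeroallergen collection points exist only in a handful of cities; each
#' region inherits the series of the closest station. Distances are
#' great-circle (haversine) when coordinates are lon/lat, Euclidean
#' otherwise. Ties are broken by station order.
#'
#' @param region_xy matrix (n_regions x 2) of region centroid coordinates.
#' @param station_xy matrix (n_stations x 2) of station coordinates.
#' @param station_series matrix (n_stations x T) of station time series.
#' @param lonlat logical; treat coordinates as lon/lat degrees.
#' @return list with `values` (n_regions x T matrix) and `station`
#'   (integer index of the assigned station per region).
#' @export
assign_nearest_station <- function(region_xy, station_xy, station_series,
                                   lonlat = FALSE) {
  region_xy <- as.matrix(region_xy); station_xy <- as.matrix(station_xy)
  station_series <- as.matrix(station_series)
  if (nrow(station_xy) == 0L) stop("no stations")
  if (nrow(station_series) != nrow(station_xy)) {
    stop("station series/coordinate mismatch")
  }
  nearest <- integer(nrow(region_xy))
  for (i in seq_len(nrow(region_xy))) {
    d <- if (lonlat) haversine(region_xy[i, ], station_xy)
         else sqrt(rowSums(sweep(station_xy, 2, region_xy[i, ])^2))
    nearest[i] <- which.min(d)  # which.min returns the first (lowest id) tie
  }
  list(values = station_series[nearest, , drop = FALSE], station = nearest)
}

haversine <- function(p, xy, radius_km = 6371) {
  to_rad <- pi / 180
  lon1 <- p[1] * to_rad; lat1 <- p[2] * to_rad
  lon2 <- xy[, 1] * to_rad; lat2 <- xy[, 2] * to_rad
  a <- sin((lat2 - lat1) / 2)^2 +
    cos(lat1) * cos(lat2) * sin((lon2 - lon1) / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Aggregate gridded exposure values to regions
#'
#' Reanalysis products arrive on a regular grid; a region's exposure is the
#' mean of the values of all grid cells whose centre falls inside the
#' region's polygon. A region containing no cell centre inherits the value
#' of the grid cell nearest to its centroid, keeping the panel complete.
#'
#' @param grid_xy matrix (n_cells x 2) of grid-cell centre coordinates.
#' @param grid_values vector (static field) or matrix (n_cells x T).
#' @param map a `region_map` with polygons.
#' @return matrix (n_regions x T); T = 1 for a vector input.
#' @export
aggregate_grid_to_region <- function(grid_xy, grid_values, map) {
  stopifnot(inherits(map, "region_map"))
  if (is.null(map$polygons)) stop("region polygons are required")
  grid_xy <- as.matrix(grid_xy)
  vals <- if (is.null(dim(grid_values))) matrix(grid_values, ncol = 1L)
          else as.matrix(grid_values)
  if (nrow(vals) != nrow(grid_xy)) stop("grid values/coordinates mismatch")
  R <- length(map$ids)
  out <- matrix(NA_real_, R, ncol(vals))
  rownames(out) <- map$ids
  for (i in seq_len(R)) {
    ring <- map$polygons[[map$ids[i]]]
    inside <- vapply(seq_len(nrow(grid_xy)), function(k) {
      point_in_polygon(grid_xy[k, ], ring)
    }, logical(1))
    if (any(inside)) {
      out[i, ] <- colMeans(vals[inside, , drop = FALSE])
    } else {
      ctr <- polygon_centroid(ring)
      d <- sqrt(rowSums(sweep(grid_xy, 2, ctr)^2))
      out[i, ] <- vals[which.min(d), ]
    }
  }
  out
}

#' Zero a series outside its in-season window
#'
#' Aeroallergen counts are only collected during the growing season; values
#' outside the window are set to zero (before standardization). The window
#' is inclusive and may wrap the year end (e.g. November-February).
#'
#' @param x numeric vector of monthly values.
#' @param months integer vector of month-of-year labels (1-12) for `x`.
#' @param window length-2 integer vector (start_month, end_month).
#' @return `x` with out-of-season entries set to 0.
#' @export
zero_out_of_season <- function(x, months, window) {
  if (length(window) != 2L || any(window < 1L) || any(window > 12L)) {
    stop("invalid season window")
  }
  if (length(months) != length(x)) stop("months/series length mismatch")
  if (any(months < 1L | months > 12L)) stop("month labels must be in 1..12")
  in_season <- if (window[1L] <= window[2L]) {
    months >= window[1L] & months <= window[2L]
  } else {
    months >= window[1L] | months <= window[2L]
  }
  x[!in_season] <- 0
  x
}

#' Population-weighted rural fraction of a region
#'
#' A unit is rural when the second character of its postal code is '0'. The
#' region covariate is the population-weighted fraction of rural units.
#'
#' @param unit_codes character vector of unit codes (length >= 2 chars).
#' @param populations nonnegative populations, one per unit.
#' @return scalar in [0, 1].
#' @export
rural_fraction <- function(unit_codes, populations) {
  unit_codes <- as.character(unit_codes)
  if (any(nchar(unit_codes) < 2L)) stop("malformed unit codes")
  if (length(populations) != length(unit_codes)) stop("length mismatch")
  if (sum(populations) <= 0) stop("zero total population")
  rural <- substr(unit_codes, 2L, 2L) == "0"
  sum(populations[rural]) / sum(populations)
}

#' Census-vintage lookup for a study year
#'
#' Census-derived covariates are piecewise constant over time: the 2006
#' census covers study years 2004-2008, the 2011 census/household survey
#' covers 2009-2014, and the 2016 census covers 2015-2017.
#'
#' @param value_2006,value_2011,value_2016 values from each census vintage.
#' @param year integer year(s) in 2004-2017.
#' @return the value(s) for the vintage covering `year`.
#' @export
census_vintage <- function(value_2006, value_2011, value_2016, year) {
  if (any(year < 2004L | year > 2017L)) stop("year out of range 2004-2017")
  ifelse(year <= 2008L, value_2006,
         ifelse(year <= 2014L, value_2011, value_2016))
}
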