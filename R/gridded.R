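#' Monthly gridded series
#'
#' The universal carrier for monthly (time, lat, lon) fields: SST, CHL, PAR,
#' NPP and all anomalies derived from them. Values are stored as a 3-d array
#' with time on the first dimension; missing data are `NA`.
#'
#' @param values numeric array `[time, lat, lon]`.
#' @param years,months integer vectors (one entry per time step) giving the
#'   calendar year and month (1-12) of each slice. The axis must be strictly
#'   increasing with exact monthly spacing (no gaps).
#' @param lat,lon numeric coordinate vectors in degrees; `lat` within
#'   \[-90, 90\].
#' @param units unit string carried through anomaly computation and I/O.
#'
#' @return An object of class `gridded_series` with fields `values`, `years`,
#'   `months`, `lat`, `lon`, `units`.
#' @export
gridded_series <- function(values, years, months, lat, lon, units) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-d array [time, lat, lon]")
  nt <- dim(values)[1L]
  years <- as.integer(years); months <- as.integer(months)
  if (length(years) != nt || length(months) != nt)
    stop("time coordinates must match dim(values)[1]")
  if (any(months < 1L | months > 12L)) stop("months must be in 1..12")
  idx <- years * 12L + (months - 1L)
  if (nt > 1L && any(diff(idx) != 1L))
    stop("time axis must be strictly increasing with monthly spacing (gap or disorder detected)")
  if (length(lat) != dim(values)[2L] || length(lon) != dim(values)[3L])
    stop("lat/lon lengths must match dim(values)[2:3]")
  if (any(lat < -90 | lat > 90)) stop("lat must lie within [-90, 90]")
  if (!is.character(units) || length(units) != 1L || !nzchar(units))
    stop("`units` must be a non-empty string")
  structure(
    list(values = values, years = years, months = months,
         lat = as.numeric(lat), lon = as.numeric(lon), units = units),
    class = "gridded_series")
}

#' @export
print.gridded_series <- function(x, ...) {
  cat(sprintf("<gridded_series> %d months (%d-%02d .. %d-%02d), %d x %d grid, units '%s'\n",
              length(x$years), x$years[1], x$months[1],
              x$years[length(x$years)], x$months[length(x$months)],
              length(x$lat), length(x$lon), x$units))
  cat(sprintf("  missing: %.2f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

is_gridded_series <- function(x) inherits(x, "gridded_series")

n_cells <- function(x) length(x$lat) * length(x$lon)

#' @keywords internal
stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  same <- identical(dim(a$values)[2:3], dim(b$values)[2:3]) &&
    isTRUE(all.equal(a$lat, b$lat)) && isTRUE(all.equal(a$lon, b$lon))
  if (!same) stop(sprintf("%s are not on the same grid", what))
  invisible(TRUE)
}

stop_if_time_mismatch <- function(a, b, what = "inputs") {
  if (!identical(a$years, b$years) || !identical(a$months, b$months))
    stop(sprintf("%s do not share a time axis", what))
  invisible(TRUE)
}

# Flatten [time, lat, lon] to a [time, cell] matrix (cells in lat-major order,
# consistent with as.vector over dims 2:3).
as_time_by_cell <- function(values) {
  d <- dim(values)
  dim(values) <- c(d[1L], d[2L] * d[3L])
  values
}

# cos-latitude area weights per cell, as a [lat, lon] matrix
cell_area_weights <- function(lat, lon) {
  w <- cos(lat * pi / 180)
  matrix(w, nrow = length(lat), ncol = length(lon))
}
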