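#' Write a monthly gridded series to CF-style NetCDF
#'
#' One variable on `(lon, lat, time)` with a `"months since <year>-01-15"`
#' time coordinate, degree lat/lon coordinates, the series units, and `NA`
#' stored as the declared fill value.
#'
#' @param series a [gridded_series()].
#' @param path output file.
#' @param varname NetCDF variable name.
#' @param fill fill value for missing data.
#' @return `path`, invisibly.
#' @export
write_gridded_netcdf <- function(series, path, varname = "field",
                                 fill = -9999) {
  stopifnot(is_gridded_series(series))
  y0 <- series$years[1]
  tvals <- (series$years - y0) * 12 + (series$months - 1)
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", series$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", series$lat)
  dtim <- ncdf4::ncdim_def("time", sprintf("months since %d-01-15", y0),
                           tvals, unlim = TRUE)
  var <- ncdf4::ncvar_def(varname, series$units, list(dlon, dlat, dtim),
                          missval = fill, prec = "double")
  nc <- ncdf4::nc_create(path, list(var))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  # internal layout is [time, lat, lon]; NetCDF wants [lon, lat, time]
  ncdf4::ncvar_put(nc, var, aperm(series$values, c(3, 2, 1)))
  invisible(path)
}

#' Read a monthly gridded series from CF-style NetCDF
#'
#' Validates that the variable sits on (lon, lat, time) style dimensions with
#' a strictly increasing, gap-free monthly time axis of the form
#' `"months since YYYY-MM-..."`; fill values become the missing mask; a
#' missing units attribute yields `"unknown"` with a warning.
#'
#' @param path NetCDF file.
#' @param variable variable name to read.
#' @return A [gridded_series()].
#' @export
read_gridded_netcdf <- function(path, variable) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  if (!variable %in% names(nc$var))
    stop(sprintf("variable '%s' not in %s", variable, path))
  v <- nc$var[[variable]]
  dimnames_ <- vapply(v$dim, function(d) d$name, "")
  need <- c("lon", "lat", "time")
  if (!all(need %in% dimnames_))
    stop("variable must have lon, lat and time dimensions")
  vals <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  # ncvar_get already maps the fill value to NA
  perm <- match(c("time", "lat", "lon"), dimnames_)
  vals <- aperm(vals, perm)
  tdim <- v$dim[[which(dimnames_ == "time")]]
  tu <- tdim$units
  m <- regmatches(tu, regexec("^months since ([0-9]{4})-([0-9]{2})", tu))[[1]]
  if (length(m) != 3L)
    stop(sprintf("time units '%s' not of the form 'months since YYYY-MM-...'", tu))
  y0 <- as.integer(m[2]); m0 <- as.integer(m[3])
  tv <- tdim$vals
  if (any(tv != round(tv))) stop("non-integer monthly time coordinate")
  if (length(tv) > 1 && any(diff(tv) != 1)) {
    gap <- which(diff(tv) != 1)[1]
    stop(sprintf("time axis is not gap-free monthly: gap after index %d (t=%s -> t=%s)",
                 gap, tv[gap], tv[gap + 1]))
  }
  idx0 <- (y0 * 12L + (m0 - 1L)) + as.integer(tv)
  years <- idx0 %/% 12L
  months <- idx0 %% 12L + 1L
  units <- v$units
  if (is.null(units) || !nzchar(units)) {
    warning(sprintf("variable '%s' has no units attribute; recording 'unknown'", variable))
    units <- "unknown"
  }
  lat <- v$dim[[which(dimnames_ == "lat")]]$vals
  lon <- v$dim[[which(dimnames_ == "lon")]]$vals
  gridded_series(vals, years, months, as.numeric(lat), as.numeric(lon), units)
}

#' Write several series into one NetCDF scene file
#'
#' @param series named list of [gridded_series()] on one grid/time axis.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scene_netcdf <- function(series, path) {
  stopifnot(length(series) >= 1, !is.null(names(series)))
  s1 <- series[[1]]
  y0 <- s1$years[1]
  tvals <- (s1$years - y0) * 12 + (s1$months - 1)
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", s1$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", s1$lat)
  dtim <- ncdf4::ncdim_def("time", sprintf("months since %d-01-15", y0), tvals)
  vars <- lapply(names(series), function(nm)
    ncdf4::ncvar_def(nm, series[[nm]]$units, list(dlon, dlat, dtim),
                     missval = -9999, prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  for (i in seq_along(series))
    ncdf4::ncvar_put(nc, vars[[i]], aperm(series[[i]]$values, c(3, 2, 1)))
  invisible(path)
}
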