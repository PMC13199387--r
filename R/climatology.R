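#' Fixed-baseline monthly climatology
#'
#' For every calendar month and grid cell, computes the mean and the
#' `q`-quantile of the series over a fixed baseline of years. The quantile is
#' the seasonally varying threshold used to label marine heatwaves; the mean
#' is the reference all anomalies are taken against. Quantiles use linear
#' interpolation between order statistics (R type 7, i.e. position
#' `1 + q * (n - 1)` in the sorted sample), recorded in the result so the
#' convention is auditable.
#'
#' @param series a [gridded_series()].
#' @param baseline integer vector of baseline years (e.g. `1998:2021`); all
#'   must be present in the series. Default: every year in the series.
#' @param q threshold probability in (0, 1); 0.90 defines MHWs.
#' @param min_samples minimum non-missing baseline values per (month, cell);
#'   below this the cell-month climatology is `NA` (with a warning).
#' @param quantile_type quantile interpolation convention as in
#'   [stats::quantile()].
#' @param detrend remove a per-cell linear trend (in time, about its center)
#'   before computing the climatology. Off by default: with a fixed recent
#'   baseline the upper-decile threshold stays well above the evolving mean,
#'   so events remain discrete extremes.
#' @param smooth_window odd width of a circular running mean applied across
#'   the 12 climatological months of both the mean and the threshold; 1
#'   (default) disables smoothing. Offered because daily-resolution MHW
#'   definitions smooth their thresholds and there is no canonical monthly
#'   analogue.
#'
#' @return An object of class `monthly_climatology`: `mean_clim` and `q90`
#'   arrays `[12, lat, lon]`, plus the baseline range, `q`, and convention.
#' @export
monthly_climatology <- function(series, baseline = NULL, q = 0.90,
                                min_samples = 2L, quantile_type = 7L,
                                detrend = FALSE, smooth_window = 1L) {
  stopifnot(is_gridded_series(series))
  if (is.null(baseline)) baseline <- sort(unique(series$years))
  if (!(q > 0 && q < 1)) stop("q must be in (0, 1)")
  if (!all(baseline %in% series$years))
    stop("baseline years outside the span of the series")
  if (smooth_window %% 2L != 1L || smooth_window < 1L)
    stop("smooth_window must be odd and >= 1")
  nlat <- length(series$lat); nlon <- length(series$lon)
  v <- as_time_by_cell(series$values)
  if (isTRUE(detrend)) {
    tt <- seq_len(nrow(v))
    v <- apply(v, 2, function(x) {
      ok <- !is.na(x)
      if (sum(ok) < 3) return(x)
      tc <- tt - mean(tt[ok])
      x - sum(tc[ok] * x[ok]) / sum(tc[ok]^2) * tc
    })
  }
  in_base <- series$years %in% baseline
  mean_clim <- array(NA_real_, c(12L, nlat, nlon))
  qq <- array(NA_real_, c(12L, nlat, nlon))
  starved <- 0L
  for (m in 1:12) {
    rows <- in_base & series$months == m
    if (!any(rows)) next
    sub <- v[rows, , drop = FALSE]
    n_ok <- colSums(!is.na(sub))
    mu <- colMeans(sub, na.rm = TRUE)
    qv <- apply(sub, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < min_samples) return(NA_real_)
      stats::quantile(x, probs = q, type = quantile_type, names = FALSE)
    })
    bad <- n_ok < min_samples
    mu[bad] <- NA_real_
    starved <- starved + sum(bad)
    mean_clim[m, , ] <- mu
    qq[m, , ] <- qv
  }
  if (starved > 0L)
    warning(sprintf("%d (month, cell) climatologies had fewer than %d baseline samples and were masked",
                    starved, min_samples))
  if (smooth_window > 1L) {
    half <- (smooth_window - 1L) %/% 2L
    smooth12 <- function(a) {
      out <- a
      for (m in 1:12) {
        win <- ((m - half - 1L):(m + half - 1L)) %% 12L + 1L
        out[m, , ] <- apply(a[win, , , drop = FALSE], c(2, 3), mean)
      }
      out
    }
    mean_clim <- smooth12(mean_clim)
    qq <- smooth12(qq)
  }
  structure(list(mean_clim = mean_clim, q90 = qq,
                 baseline = range(baseline), q = q,
                 quantile_type = quantile_type,
                 detrend = isTRUE(detrend), smooth_window = smooth_window,
                 lat = series$lat, lon = series$lon),
            class = "monthly_climatology")
}

#' Anomalies relative to a monthly climatology
#'
#' Subtracts the per-calendar-month climatological mean from every time
#' slice. Units are preserved; the anomaly is `NA` wherever the value or the
#' climatology is missing. Over the baseline the per-(month, cell) anomaly
#' mean is zero to floating precision.
#'
#' @param series a [gridded_series()].
#' @param clim a [monthly_climatology()] on the same grid.
#' @return A [gridded_series()] of anomalies.
#' @export
anomalies <- function(series, clim) {
  stopifnot(is_gridded_series(series), inherits(clim, "monthly_climatology"))
  if (!isTRUE(all.equal(series$lat, clim$lat)) ||
      !isTRUE(all.equal(series$lon, clim$lon)))
    stop("series and climatology are not on the same grid")
  out <- series$values - clim$mean_clim[series$months, , , drop = FALSE]
  gridded_series(out, series$years, series$months, series$lat, series$lon,
                 series$units)
}

#' Label every cell-month as MHW, moderate warm, or other
#'
#' Applies the seasonally varying threshold of a fixed-baseline climatology:
#' a cell-month is a marine heatwave (`MHW`) when SST strictly exceeds the
#' `q`-quantile threshold; a moderate warm month (`SSTA_PLUS`) when SST
#' strictly exceeds the climatological mean but does not exceed the
#' threshold; `OTHER` when at or below the mean. Both comparisons are strict,
#' so a value exactly at the threshold is `SSTA_PLUS` and one exactly at the
#' mean is `OTHER`. Missing SST or missing climatology propagates to a
#' missing label.
#'
#' @param sst a [gridded_series()] of SST.
#' @param clim a [monthly_climatology()] from a fixed baseline (which may
#'   differ from the labeled span).
#' @return An object of class `condition_labels`: integer array
#'   `[time, lat, lon]` in `$label` with codes `OTHER = 0`, `SSTA_PLUS = 1`,
#'   `MHW = 2`, `NA` for missing, plus the code table and coordinates.
#' @export
label_conditions <- function(sst, clim) {
  stopifnot(is_gridded_series(sst), inherits(clim, "monthly_climatology"))
  if (!isTRUE(all.equal(sst$lat, clim$lat)) ||
      !isTRUE(all.equal(sst$lon, clim$lon)))
    stop("sst and climatology are not on the same grid")
  mu <- clim$mean_clim[sst$months, , , drop = FALSE]
  thr <- clim$q90[sst$months, , , drop = FALSE]
  lab <- array(NA_integer_, dim(sst$values))
  ok <- !is.na(sst$values) & !is.na(mu) & !is.na(thr)
  lab[ok] <- 0L
  lab[ok & sst$values > mu] <- 1L
  lab[ok & sst$values > thr] <- 2L
  structure(list(label = lab,
                 codes = c(OTHER = 0L, SSTA_PLUS = 1L, MHW = 2L),
                 years = sst$years, months = sst$months,
                 lat = sst$lat, lon = sst$lon),
            class = "condition_labels")
}

#' @export
print.condition_labels <- function(x, ...) {
  tab <- table(factor(x$label, levels = x$codes, labels = names(x$codes)),
               useNA = "always")
  cat("<condition_labels>\n")
  print(tab)
  invisible(x)
}

# logical [time, lat, lon] mask of months in a named condition
condition_mask <- function(labels, condition) {
  stopifnot(inherits(labels, "condition_labels"))
  if (!condition %in% names(labels$codes))
    stop(sprintf("unknown condition '%s' (expected one of %s)", condition,
                 paste(names(labels$codes), collapse = ", ")))
  m <- labels$label == labels$codes[[condition]]
  m[is.na(m)] <- FALSE
  m
}
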