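#' Named region mask with area weights
#'
#' A boolean cell mask (e.g. an LME, a WBCE/EBUS regime, a basin) carrying
#' cos-latitude area weights. Masks are consumed, not derived: supply them as
#' logical matrices on the data grid (rasterize polygons by cell-center
#' containment upstream if needed).
#'
#' @param name region name.
#' @param mask logical `[lat, lon]` matrix with at least one `TRUE` cell.
#' @param lat latitude vector (degrees) matching the mask rows.
#' @param group optional grouping tag (e.g. continent).
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(name, mask, lat, group = NA_character_) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("`mask` must be a logical matrix")
  if (nrow(mask) != length(lat)) stop("mask rows must match `lat`")
  mask[is.na(mask)] <- FALSE
  if (!any(mask)) stop("region mask has no TRUE cell")
  w <- matrix(cos(lat * pi / 180), nrow(mask), ncol(mask))
  if (any(w[mask] <= 0)) stop("area weights must be positive inside the region (|lat| < 90)")
  structure(list(name = name, mask = mask, lat = lat, weights = w,
                 group = group),
            class = "region_mask")
}

#' Box-plot-style summary of a field over a region
#'
#' Area-weighted mean plus unweighted distributional statistics of the cell
#' values inside a region: quartiles (linear-interpolation convention,
#' [stats::quantile()] type 7), the median, and whiskers at 1.5 x IQR clipped
#' to the observed range — the usual box-and-whisker recipe. `NA` cells are
#' excluded.
#'
#' @param field numeric `[lat, lon]` matrix of per-cell values.
#' @param mask a [region_mask()].
#' @param condition optional condition tag copied into the output.
#' @return A one-row `data.frame`: region, condition, n_cells, weighted_mean,
#'   q1, median, q3, whisker_lo, whisker_hi.
#' @export
regional_summary <- function(field, mask, condition = NA_character_) {
  stopifnot(inherits(mask, "region_mask"))
  if (!is.matrix(field) || !identical(dim(field), dim(mask$mask)))
    stop("field and mask are not on the same grid")
  sel <- mask$mask & !is.na(field)
  if (!any(sel)) stop(sprintf("region '%s' is empty after masking", mask$name))
  x <- field[sel]; w <- mask$weights[sel]
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- qs[3] - qs[1]
  data.frame(region = mask$name, condition = condition, n_cells = length(x),
             weighted_mean = sum(w * x) / sum(w),
             q1 = qs[1], median = qs[2], q3 = qs[3],
             whisker_lo = max(min(x), qs[1] - 1.5 * iqr),
             whisker_hi = min(max(x), qs[3] + 1.5 * iqr))
}

#' Percent change of a field under a condition
#'
#' Per cell: `100 * (mean over condition months - local long-term mean) /
#' local long-term mean`, the "change ratio" of a condition composite
#' against the cell's own mean state over the full analysis span. Cells with
#' fewer than `min_months` condition months, or a long-term mean below the
#' floor, are masked (the count of floor-masked cells is attached as
#' attribute `n_floor_masked`).
#'
#' @param series a [gridded_series()] (raw field, e.g. NPP).
#' @param labels a [label_conditions()] result on the same axes.
#' @param condition condition name.
#' @param min_months minimum condition months per cell (default 3).
#' @param denom_floor smallest usable |long-term mean|; default
#'   `1e-6 * mean(|values|)`.
#' @return A `[lat, lon]` matrix of percent changes.
#' @export
change_ratio <- function(series, labels, condition, min_months = 3L,
                         denom_floor = NULL) {
  stopifnot(is_gridded_series(series), inherits(labels, "condition_labels"))
  if (!identical(dim(series$values), dim(labels$label)))
    stop("series and labels are not on the same grid/time axis")
  mask <- condition_mask(labels, condition) & !is.na(series$values)
  sel <- series$values
  sel[!mask] <- NA_real_
  cond_mean <- apply(sel, c(2, 3), mean, na.rm = TRUE)
  n_m <- apply(mask, c(2, 3), sum)
  long_mean <- apply(series$values, c(2, 3), mean, na.rm = TRUE)
  if (is.null(denom_floor))
    denom_floor <- 1e-6 * mean(abs(series$values), na.rm = TRUE)
  out <- 100 * (cond_mean - long_mean) / long_mean
  out[n_m < min_months] <- NA_real_
  floored <- is.finite(long_mean) & abs(long_mean) < denom_floor
  out[floored] <- NA_real_
  attr(out, "n_floor_masked") <- sum(floored)
  out
}

#' Latitude-band area-weighted means
#'
#' cos-latitude-weighted mean of a per-cell field within latitude bands. A
#' cell belongs to the band whose interval contains its center latitude,
#' lower edge inclusive (the topmost band also includes its upper edge).
#' Because every cell falls in exactly one band, the weight-combined band
#' means reproduce the global weighted mean exactly.
#'
#' @param field numeric `[lat, lon]` matrix.
#' @param lat latitude vector (degrees) matching the field rows.
#' @param edges increasing vector of band edges in degrees, e.g.
#'   `c(-80, -45, 45, 80)`.
#' @return A `data.frame` with `band_lo`, `band_hi`, `weighted_mean`,
#'   `weight`, `n_cells`; empty bands carry `NA` means and zero weight.
#' @export
band_summary <- function(field, lat, edges) {
  if (!is.matrix(field) || nrow(field) != length(lat))
    stop("field rows must match `lat`")
  if (is.unsorted(edges, strictly = TRUE)) stop("band edges must be strictly increasing")
  nb <- length(edges) - 1L
  if (nb < 1L) stop("need at least two band edges")
  w <- matrix(cos(lat * pi / 180), nrow(field), ncol(field))
  latm <- matrix(lat, nrow(field), ncol(field))
  out <- data.frame(band_lo = edges[-length(edges)], band_hi = edges[-1],
                    weighted_mean = NA_real_, weight = 0, n_cells = 0L)
  for (b in seq_len(nb)) {
    hi_ok <- if (b == nb) latm <= edges[b + 1] else latm < edges[b + 1]
    sel <- latm >= edges[b] & hi_ok & !is.na(field)
    out$n_cells[b] <- sum(sel)
    if (any(sel)) {
      out$weight[b] <- sum(w[sel])
      out$weighted_mean[b] <- sum(w[sel] * field[sel]) / out$weight[b]
    }
  }
  out
}

#' Summaries of baseline and anomaly fields by response class
#'
#' For each requested response class (MHW-enhanced, MHW-inhibited), computes
#' [regional_summary()]-style statistics of a baseline field and of an
#' anomaly composite over the class's cells — the box-summary pairs used to
#' contrast the mean environmental state of enhanced vs inhibited regions.
#'
#' @param baseline numeric `[lat, lon]` matrix (e.g. climatological SST,
#'   MLD, CHL or nutrient state).
#' @param anomaly numeric `[lat, lon]` matrix (e.g. the MHW-month anomaly
#'   composite of the same quantity).
#' @param classes a [response_class_map()].
#' @param which_classes classes to summarize; an empty class is an error.
#' @return A tidy `data.frame`: class, field (`"baseline"`/`"anomaly"`) and
#'   the [regional_summary()] columns.
#' @export
class_conditioned_summary <- function(baseline, anomaly, classes,
                                      which_classes = c("ENHANCED", "INHIBITED")) {
  stopifnot(inherits(classes, "response_class_map"))
  rows <- list()
  for (cl in which_classes) {
    sel <- !is.na(classes$class) & classes$class == cl
    if (!any(sel)) stop(sprintf("class '%s' is empty", cl))
    rm_ <- region_mask(cl, sel, classes$lat)
    for (fn in c("baseline", "anomaly")) {
      f <- if (fn == "baseline") baseline else anomaly
      s <- regional_summary(f, rm_)
      s$region <- NULL
      rows[[length(rows) + 1L]] <- cbind(data.frame(class = cl, field = fn), s)
    }
  }
  do.call(rbind, rows)
}

#' Convert mg C m^-2 day^-1 to g C m^-2 year^-1
#'
#' The internal NPP unit is mg C m^-2 day^-1; figures are conventionally
#' reported in g C m^-2 year^-1 (x 365 / 1000).
#'
#' @param x values in mg C m^-2 day^-1.
#' @return Values in g C m^-2 year^-1.
#' @export
mgc_day_to_gc_year <- function(x) x * 365 / 1000
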