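#' Dominant-driver classification per cell and condition
#'
#' Compares the magnitude of the composited SST-dependent and
#' SST-independent components at every cell: the class is `SST_DEPENDENT`
#' when `|mean sst_dependent|` strictly exceeds `|mean sst_independent|`
#' during the condition months, `SST_INDEPENDENT` otherwise. An exact tie is
#' classified `SST_INDEPENDENT` (the conservative choice for a statistic
#' about growing SST dependence) and flagged. Masked composites give
#' `UNDEFINED`.
#'
#' @param composites a single [composite_components()] result, or a named
#'   list of them (one per condition).
#' @param metric `"mean"` (default) compares `|mean|` composites, matching
#'   budget maps of mean component values per condition; `"variance"`
#'   compares the within-condition variances of the two grouped series
#'   (a variance-share view of dominance).
#' @return For one composite: a list of class `dominance_map` with `class`
#'   (character `[lat, lon]` matrix), `dep_mag`, `indep_mag`, `tie` flags,
#'   the condition and coordinates. For a list input: a named list of such
#'   objects.
#' @export
dominance_map <- function(composites, metric = c("mean", "variance")) {
  metric <- match.arg(metric)
  if (inherits(composites, "component_composite"))
    return(dominance_one(composites, metric))
  if (is.list(composites) &&
      all(vapply(composites, inherits, TRUE, "component_composite")))
    return(lapply(composites, dominance_one, metric = metric))
  stop("`composites` must be a component_composite or a list of them")
}

dominance_one <- function(comp, metric = "mean") {
  if (metric == "variance") {
    dep <- comp$sst_dependent_var
    indep <- comp$sst_independent_var
  } else {
    dep <- abs(comp$sst_dependent)
    indep <- abs(comp$sst_independent)
  }
  cls <- matrix("UNDEFINED", nrow(dep), ncol(dep))
  ok <- !is.na(dep) & !is.na(indep)
  cls[ok & dep > indep] <- "SST_DEPENDENT"
  cls[ok & dep <= indep] <- "SST_INDEPENDENT"
  tie <- ok & dep == indep
  structure(list(class = cls, dep_mag = dep, indep_mag = indep, tie = tie,
                 condition = comp$condition, lat = comp$lat, lon = comp$lon),
            class = "dominance_map")
}

#' MHW-enhanced / MHW-inhibited response classification
#'
#' Computes the per-cell Pearson correlation between the NPP anomaly and the
#' SST anomaly and classifies cells by its sign and significance: `ENHANCED`
#' when the correlation is significantly positive, `INHIBITED` when
#' significantly negative, `NEUTRAL` otherwise. Significance is a two-sided
#' t test (`t = r sqrt(df / (1 - r^2))`, `df = n - 2`) at level `alpha_sig`
#' (default 0.10, i.e. a 90% confidence level), with no autocorrelation or
#' multiple-testing correction. All months enter by default; pass `labels`
#' and `condition` to restrict the sample to one condition's months.
#'
#' @param nppa,ssta aligned [gridded_series()] anomaly fields.
#' @param alpha_sig two-sided significance level in (0, 1\].
#' @param labels optional [label_conditions()] result.
#' @param condition optional condition name restricting the sample.
#' @param min_n minimum complete months per cell (default 8); below it, or
#'   with zero variance in either series, the cell is `UNDEFINED`.
#' @param effective_df shrink each cell's degrees of freedom for serial
#'   correlation with the lag-1 rule
#'   `n_eff = n (1 - r1x r1y) / (1 + r1x r1y)` before the t test. Off by
#'   default (the plain test, no autocorrelation correction).
#' @return An object of class `response_class_map`: `[lat, lon]` matrices
#'   `r`, `p`, `n` and the character `class` matrix, plus coordinates.
#' @export
response_class_map <- function(nppa, ssta, alpha_sig = 0.10, labels = NULL,
                               condition = NULL, min_n = 8L,
                               effective_df = FALSE) {
  stop_if_grid_mismatch(nppa, ssta, "anomaly fields")
  stop_if_time_mismatch(nppa, ssta, "anomaly fields")
  if (!(alpha_sig > 0 && alpha_sig <= 1)) stop("alpha_sig must be in (0, 1]")
  x <- as_time_by_cell(ssta$values)
  y <- as_time_by_cell(nppa$values)
  if (!is.null(labels)) {
    if (is.null(condition)) stop("`condition` required when `labels` given")
    keep <- as_time_by_cell(condition_mask(labels, condition) * 1) > 0
    x[!keep] <- NA_real_
    y[!keep] <- NA_real_
  }
  ok <- is.finite(x) & is.finite(y)
  x[!ok] <- NA_real_; y[!ok] <- NA_real_
  n <- colSums(ok)
  mx <- colMeans(x, na.rm = TRUE); my <- colMeans(y, na.rm = TRUE)
  xc <- sweep(x, 2, mx); yc <- sweep(y, 2, my)
  xc[!ok] <- 0; yc[!ok] <- 0
  sxx <- colSums(xc^2); syy <- colSums(yc^2); sxy <- colSums(xc * yc)
  r <- rep(NA_real_, length(n))
  valid <- n >= max(min_n, 3L) & sxx > 0 & syy > 0
  r[valid] <- sxy[valid] / sqrt(sxx[valid] * syy[valid])
  r <- pmin(pmax(r, -1), 1)
  n_eff <- n
  if (isTRUE(effective_df)) {
    lag1 <- function(m, ok2) {
      a <- m[-nrow(m), , drop = FALSE]; b <- m[-1, , drop = FALSE]
      both <- ok2[-nrow(m), , drop = FALSE] & ok2[-1, , drop = FALSE]
      a[!both] <- NA; b[!both] <- NA
      am <- colMeans(a, na.rm = TRUE); bm <- colMeans(b, na.rm = TRUE)
      ac <- sweep(a, 2, am); bc <- sweep(b, 2, bm)
      ac[!both] <- 0; bc[!both] <- 0
      colSums(ac * bc) / pmax(sqrt(colSums(ac^2) * colSums(bc^2)),
                              .Machine$double.eps)
    }
    prod1 <- pmin(pmax(lag1(x, ok) * lag1(y, ok), -0.99), 0.99)
    n_eff <- pmax(n * (1 - prod1) / (1 + prod1), 4)
  }
  df <- n_eff - 2
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[abs(r) == 1] <- 0
  cls <- rep("UNDEFINED", length(n))
  cls[valid] <- "NEUTRAL"
  cls[valid & r > 0 & p < alpha_sig] <- "ENHANCED"
  cls[valid & r < 0 & p < alpha_sig] <- "INHIBITED"
  nlat <- length(ssta$lat); nlon <- length(ssta$lon)
  shape <- function(v) matrix(v, nlat, nlon)
  structure(list(r = shape(r), p = shape(ifelse(valid, p, NA_real_)),
                 n = shape(n), class = shape(cls),
                 alpha_sig = alpha_sig, lat = ssta$lat, lon = ssta$lon),
            class = "response_class_map")
}

#' Area fraction of a class on the sphere
#'
#' cos(latitude)-weighted area of the cells carrying `target_class`, divided
#' by the weighted area of all defined (non-`UNDEFINED`, non-`NA`) cells.
#' Fractions over the full class set sum to 1.
#'
#' @param class_map a character `[lat, lon]` matrix of class names, or an
#'   object with `$class`, `$lat` fields ([dominance_map()],
#'   [response_class_map()]).
#' @param target_class class name to measure.
#' @param lat latitude vector (degrees), one per row of the class matrix;
#'   taken from the object when available.
#' @return A fraction in \[0, 1\].
#' @export
area_fraction <- function(class_map, target_class, lat = NULL) {
  if (is.list(class_map) && !is.null(class_map$class)) {
    if (is.null(lat)) lat <- class_map$lat
    class_map <- class_map$class
  }
  if (is.null(lat)) stop("`lat` required when passing a bare class matrix")
  if (!is.matrix(class_map) || nrow(class_map) != length(lat))
    stop("class matrix rows must match `lat`")
  w <- matrix(cos(lat * pi / 180), nrow(class_map), ncol(class_map))
  defined <- !is.na(class_map) & class_map != "UNDEFINED"
  if (!any(defined)) stop("no defined cells in class map")
  sum(w[defined & class_map == target_class]) / sum(w[defined])
}
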