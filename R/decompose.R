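#' Two-stage decomposition of an NPP anomaly series at one cell
#'
#' Stage 1 regresses the chlorophyll and PAR anomalies on the SST anomaly
#' (ordinary least squares, no intercept, anomaly inputs):
#' \deqn{CHLA = \alpha\,SSTA + CHLA_{res}, \quad
#'       PARA = \beta\,SSTA + PARA_{res}.}
#' Stage 2 partitions the NPP anomaly into six terms,
#' \deqn{NPPA = a\,SSTA + b\,CHLA_{sst} + c\,PARA_{sst}
#'       + d\,CHLA_{res} + e\,PARA_{res} + NPPA_{res},}
#' grouped as SST-dependent (first three) and SST-independent (last three).
#'
#' Because \eqn{CHLA_{sst} = \alpha\,SSTA} and \eqn{PARA_{sst} = \beta\,SSTA}
#' are exactly proportional to SSTA, the three SST-linked coefficients are
#' not separately identifiable from a joint regression on all five
#' regressors. The fit therefore runs on the full-rank design
#' `(SSTA, CHLA_res, PARA_res)`, giving the total SSTA slope and `d`, `e`,
#' and allocates the SSTA slope across the three pathways with the
#' convention `b = d`, `c = e` (the NPP response to a chlorophyll or light
#' fluctuation does not depend on whether SST drove it, as in any
#' multiplicative NPP model), so `a = total - d*alpha - e*beta`. The
#' six-term budget sums to NPPA exactly regardless of the allocation.
#'
#' Missing months are dropped listwise across the four series so every
#' fitted quantity shares one sample. Numerically zero-variance regressors
#' (e.g. residuals on a zero-noise scene) get coefficient 0 and a flag; a
#' zero-variance SSTA makes `alpha`, `beta`, `a` degenerate (set to 0, all
#' variance on the residuals).
#'
#' @param ssta,chla,para,nppa aligned numeric anomaly series (same length),
#'   computed against the same climatology.
#' @param min_n minimum number of complete months required to fit (default
#'   24, i.e. df >= 18 for the joint stage-2 fit plus stage-1 slopes).
#' @param intercept include intercepts in both stages (default `FALSE`:
#'   anomalies have near-zero baseline mean by construction). A fitted
#'   stage-2 intercept is folded into `NPPA_res` so the budget still sums to
#'   NPPA.
#' @param subset optional logical vector (same length as the series)
#'   restricting the fit sample, e.g. to one condition's months for a
#'   per-condition refit sensitivity analysis. Component series are returned
#'   only on the fit sample. Default: all months.
#' @return An object of class `cell_decomposition`: coefficients `alpha`,
#'   `beta`, `a`-`e`; component series (`chla_sst`, `chla_res`, `para_sst`,
#'   `para_res`), the six NPPA terms, grouped `sst_dependent` and
#'   `sst_independent` series; diagnostics `n`, `r2`, `flags`. Component
#'   series are `NA` on incomplete months. If fewer than `min_n` complete
#'   months exist the cell is masked (`ok = FALSE`, all-`NA` output).
#' @export
decompose_cell <- function(ssta, chla, para, nppa, min_n = 24L,
                           intercept = FALSE, subset = NULL) {
  n_all <- length(ssta)
  if (length(chla) != n_all || length(para) != n_all || length(nppa) != n_all)
    stop("input series must share one length")
  ok_t <- is.finite(ssta) & is.finite(chla) & is.finite(para) & is.finite(nppa)
  if (!is.null(subset)) {
    if (length(subset) != n_all) stop("`subset` must match the series length")
    ok_t <- ok_t & !is.na(subset) & subset
  }
  n <- sum(ok_t)
  empty <- rep(NA_real_, n_all)
  out <- list(alpha = NA_real_, beta = NA_real_, a = NA_real_, b = NA_real_,
              c = NA_real_, d = NA_real_, e = NA_real_,
              chla_sst = empty, chla_res = empty,
              para_sst = empty, para_res = empty,
              terms = NULL, sst_dependent = empty, sst_independent = empty,
              n = n, r2 = NA_real_, flags = character(0), ok = FALSE,
              intercepts = NULL)
  class(out) <- "cell_decomposition"
  if (n < min_n) {
    out$flags <- "insufficient_sample"
    return(out)
  }
  s <- ssta[ok_t]; ch <- chla[ok_t]; pa <- para[ok_t]; np <- nppa[ok_t]

  ols1 <- function(y, x) {
    # simple no-intercept slope; with intercept, centered slope + intercept
    if (intercept) {
      xm <- mean(x); ym <- mean(y)
      sxx <- sum((x - xm)^2)
      if (sxx <= 0) return(c(slope = 0, icpt = ym))
      b <- sum((x - xm) * (y - ym)) / sxx
      c(slope = b, icpt = ym - b * xm)
    } else {
      sxx <- sum(x^2)
      if (sxx <= 0) return(c(slope = 0, icpt = 0))
      c(slope = sum(x * y) / sxx, icpt = 0)
    }
  }

  scale_ref <- sqrt(mean(s^2) + mean(ch^2) + mean(pa^2))
  degenerate_sst <- sqrt(mean(s^2)) <= 1e-12 * max(scale_ref, 1)
  if (degenerate_sst) {
    out$flags <- c(out$flags, "degenerate_sst")
    alpha <- 0; beta <- 0; i_ch <- 0; i_pa <- 0
  } else {
    f1 <- ols1(ch, s); alpha <- f1[["slope"]]; i_ch <- f1[["icpt"]]
    f2 <- ols1(pa, s); beta <- f2[["slope"]]; i_pa <- f2[["icpt"]]
  }
  ch_sst <- alpha * s
  pa_sst <- beta * s
  ch_res <- ch - ch_sst - i_ch
  pa_res <- pa - pa_sst - i_pa

  # stage 2 on the identifiable full-rank design
  X <- cbind(ssta = s, chla_res = ch_res, para_res = pa_res)
  if (intercept) X <- cbind(X, `(icpt)` = rep(1, n))
  col_rms <- sqrt(colMeans(X^2))
  keep <- col_rms > 1e-8 * max(col_rms, 1e-300)
  if (degenerate_sst) keep["ssta"] <- FALSE
  coef_full <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (any(keep)) {
    fit <- stats::lm.fit(X[, keep, drop = FALSE], np)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    coef_full[names(cf)] <- cf
  }
  if (!all(keep))
    out$flags <- c(out$flags, paste0("dropped_", colnames(X)[!keep]))
  a_tot <- coef_full[["ssta"]]
  d <- coef_full[["chla_res"]]
  e <- coef_full[["para_res"]]
  i_np <- if (intercept) coef_full[["(icpt)"]] else 0
  b <- d; c_ <- e
  a <- a_tot - d * alpha - e * beta

  t_a <- a * s
  t_b <- b * ch_sst
  t_c <- c_ * pa_sst
  t_d <- d * ch_res
  t_e <- e * pa_res
  t_res <- np - (t_a + t_b + t_c + t_d + t_e)

  fill <- function(x) { v <- empty; v[ok_t] <- x; v }
  out$alpha <- alpha; out$beta <- beta
  out$a <- a; out$b <- b; out$c <- c_; out$d <- d; out$e <- e
  out$chla_sst <- fill(ch_sst); out$chla_res <- fill(ch_res)
  out$para_sst <- fill(pa_sst); out$para_res <- fill(pa_res)
  out$terms <- list(a_ssta = fill(t_a), b_chla_sst = fill(t_b),
                    c_para_sst = fill(t_c), d_chla_res = fill(t_d),
                    e_para_res = fill(t_e), nppa_res = fill(t_res))
  out$sst_dependent <- fill(t_a + t_b + t_c)
  out$sst_independent <- fill(t_d + t_e + t_res)
  ss_tot <- sum(np^2)
  out$r2 <- if (ss_tot > 0) 1 - sum(t_res^2) / ss_tot else NA_real_
  out$intercepts <- c(chl = i_ch, par = i_pa, npp = i_np)
  out$ok <- TRUE
  out
}

#' Grid-wise decomposition
#'
#' Applies [decompose_cell()] to every grid cell of four aligned anomaly
#' fields. Cells failing the minimum-sample rule are masked; degenerate and
#' dropped-regressor flags are tallied.
#'
#' @param ssta,chla,para,nppa aligned [gridded_series()] anomaly fields.
#' @param min_n,intercept as in [decompose_cell()].
#' @param subset optional logical `[time, lat, lon]` array restricting every
#'   cell's fit sample (e.g. a condition mask for per-condition refits).
#' @return An object of class `grid_decomposition` with coefficient maps
#'   (`[lat, lon]` matrices `alpha`, `beta`, `a`-`e`, `r2`, `n`), component
#'   arrays `[time, lat, lon]` (`sst_dependent`, `sst_independent`, `nppa`,
#'   and the six `terms`), a per-cell flag summary, and the coordinates.
#' @export
decompose_grid <- function(ssta, chla, para, nppa, min_n = 24L,
                           intercept = FALSE, subset = NULL) {
  for (x in list(chla, para, nppa)) {
    stop_if_grid_mismatch(ssta, x, "anomaly fields")
    stop_if_time_mismatch(ssta, x, "anomaly fields")
  }
  if (all(is.na(ssta$values))) stop("all-missing SSTA field")
  nlat <- length(ssta$lat); nlon <- length(ssta$lon)
  nt <- length(ssta$years); ncell <- nlat * nlon
  vs <- as_time_by_cell(ssta$values); vc <- as_time_by_cell(chla$values)
  vp <- as_time_by_cell(para$values); vn <- as_time_by_cell(nppa$values)

  cmap <- function() matrix(NA_real_, nlat, nlon)
  maps <- list(alpha = cmap(), beta = cmap(), a = cmap(), b = cmap(),
               c = cmap(), d = cmap(), e = cmap(), r2 = cmap(), n = cmap())
  arr <- function() array(NA_real_, c(nt, nlat, nlon))
  dep <- arr(); indep <- arr()
  term_names <- c("a_ssta", "b_chla_sst", "c_para_sst", "d_chla_res",
                  "e_para_res", "nppa_res")
  terms <- stats::setNames(lapply(term_names, function(i) arr()), term_names)
  flags <- vector("list", ncell)
  ok <- logical(ncell)
  sub <- if (is.null(subset)) NULL else as_time_by_cell(subset * 1) > 0
  for (j in seq_len(ncell)) {
    cd <- decompose_cell(vs[, j], vc[, j], vp[, j], vn[, j],
                         min_n = min_n, intercept = intercept,
                         subset = if (is.null(sub)) NULL else sub[, j])
    flags[[j]] <- cd$flags
    ok[j] <- cd$ok
    ij <- c((j - 1L) %% nlat + 1L, (j - 1L) %/% nlat + 1L)
    maps$n[ij[1], ij[2]] <- cd$n
    if (!cd$ok) next
    for (nm in c("alpha", "beta", "a", "b", "c", "d", "e", "r2"))
      maps[[nm]][ij[1], ij[2]] <- cd[[nm]]
    dep[, ij[1], ij[2]] <- cd$sst_dependent
    indep[, ij[1], ij[2]] <- cd$sst_independent
    for (nm in term_names) terms[[nm]][, ij[1], ij[2]] <- cd$terms[[nm]]
  }
  flag_tab <- table(unlist(flags))
  structure(list(maps = maps, sst_dependent = dep, sst_independent = indep,
                 terms = terms,
                 nppa = nppa$values, ok = matrix(ok, nlat, nlon),
                 flag_summary = flag_tab, n_masked = sum(!ok),
                 years = ssta$years, months = ssta$months,
                 lat = ssta$lat, lon = ssta$lon,
                 min_n = min_n, intercept = intercept),
            class = "grid_decomposition")
}

#' @export
print.grid_decomposition <- function(x, ...) {
  cat(sprintf("<grid_decomposition> %d x %d cells, %d months; %d masked\n",
              length(x$lat), length(x$lon), length(x$years), x$n_masked))
  if (length(x$flag_summary)) print(x$flag_summary)
  invisible(x)
}

#' Condition-composited decomposition components
#'
#' For every cell, the time mean of the NPP anomaly and of its grouped
#' SST-dependent and SST-independent components over the months carrying a
#' given condition label (the regression itself is fit once over all
#' months). Cells with fewer condition months than `min_months` are masked.
#' By construction `nppa = sst_dependent + sst_independent` holds for the
#' composites as it does month by month.
#'
#' @param decomp a [decompose_grid()] result.
#' @param labels a [label_conditions()] result on the same grid/time axis.
#' @param condition `"MHW"`, `"SSTA_PLUS"`, or `"OTHER"`.
#' @param min_months minimum number of condition months per cell (default 3).
#' @return An object of class `component_composite`: `[lat, lon]` matrices
#'   `nppa`, `sst_dependent`, `sst_independent` (condition-month means),
#'   their within-condition variances (`*_var`, for the variance-share
#'   dominance metric), `n_months`, plus the condition and coordinates.
#' @export
composite_components <- function(decomp, labels, condition, min_months = 3L) {
  stopifnot(inherits(decomp, "grid_decomposition"),
            inherits(labels, "condition_labels"))
  if (!identical(dim(decomp$nppa), dim(labels$label)))
    stop("decomposition and labels are not on the same grid/time axis")
  # composite over condition months where the decomposition exists, so the
  # three composites share one sample and additivity stays exact
  mask <- condition_mask(labels, condition) & !is.na(decomp$sst_dependent)
  comp_of <- function(a) {
    x <- a
    x[!mask] <- NA_real_
    apply(x, c(2, 3), function(v) mean(v, na.rm = TRUE))
  }
  n_m <- apply(mask, c(2, 3), sum)
  var_of <- function(a) {
    x <- a
    x[!mask] <- NA_real_
    apply(x, c(2, 3), function(v) stats::var(v[!is.na(v)]))
  }
  dep <- comp_of(decomp$sst_dependent)
  indep <- comp_of(decomp$sst_independent)
  npp <- comp_of(decomp$nppa)
  dep_v <- var_of(decomp$sst_dependent)
  indep_v <- var_of(decomp$sst_independent)
  drop <- n_m < min_months
  for (x in c("dep", "indep", "npp", "dep_v", "indep_v")) {
    tmp <- get(x); tmp[drop] <- NA_real_; assign(x, tmp)
  }
  structure(list(nppa = npp, sst_dependent = dep, sst_independent = indep,
                 sst_dependent_var = dep_v, sst_independent_var = indep_v,
                 n_months = n_m, condition = condition,
                 lat = decomp$lat, lon = decomp$lon),
            class = "component_composite")
}
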