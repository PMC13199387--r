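#' Configuration of a synthetic monthly ocean scene
#'
#' Defines the forward model the decomposition assumes, with known
#' ground-truth coefficients. SST is a latitude-dependent seasonal cycle plus
#' an AR(1) anomaly; CHL and PAR anomalies are a linear-in-SSTA part plus
#' independent noise; the NPP anomaly is the linear combination of the SSTA
#' pathway, the SST-projected CHL/PAR parts, the residual CHL/PAR parts, and
#' independent noise:
#' \deqn{CHLA = \alpha\,SSTA + \epsilon_{chl}, \quad
#'       PARA = \beta\,SSTA + \epsilon_{par}}
#' \deqn{NPPA = a\,SSTA + b\,\alpha\,SSTA + c\,\beta\,SSTA +
#'       d\,\epsilon_{chl} + e\,\epsilon_{par} + \epsilon_{npp}}
#' Anomalies ride on smooth positive base fields so CHL and NPP stay
#' physical.
#'
#' Defaults emulate a 21-year (252-month) analysis record on a coarse global
#' band: an AR(1) SST anomaly with innovation SD 0.8 degC and lag-1
#' coefficient 0.5; a mild chlorophyll loss per degree of warming
#' (`alpha_true = -0.05` mg m^-3 degC^-1) and a clear-sky PAR gain
#' (`beta_true = 0.8` mol photons m^-2 d^-1 degC^-1); NPP responses on the
#' VGPM scale (`b_true = d_true = 450` mg C m^-2 d^-1 per mg chl m^-3,
#' `c_true = e_true = 4` per mol photon, direct thermal slope `a_true = 15`).
#' The equalities `b = d` and `c = e` reflect that a multiplicative NPP model
#' responds to a chlorophyll or light fluctuation identically whether or not
#' SST drove it; they also make all five second-stage coefficients
#' identifiable (see [decompose_cell()]).
#'
#' @param n_years number of simulated years (>= 2); 12 months each.
#' @param n_lat,n_lon grid size; at least 2 cells in total.
#' @param lat,lon coordinate vectors (defaults: `n_lat` centers in
#'   \[-80, 80\], `n_lon` centers in \[0, 360)).
#' @param start_year first calendar year of the record.
#' @param sst_mean,sst_seasonal_amp climatological SST mean and seasonal
#'   amplitude (degC), scalar or per-latitude vector. Defaults warm the
#'   tropics and cool the poles, with a stronger cycle at mid-latitudes.
#' @param ar1_phi lag-1 autoregression of the SST anomaly, |phi| < 1.
#' @param sst_noise_sd SD of the AR(1) innovations (degC).
#' @param mhw_boost scale (degC) of an occasional extra warm-tail innovation:
#'   with probability 0.05 an exponential bump of this mean is added (and the
#'   unconditional mean re-centred), fattening the upper tail while keeping
#'   the anomaly stationary. 0 disables it.
#' @param alpha_true,beta_true stage-1 slopes of CHLA and PARA on SSTA.
#' @param a_true,b_true,c_true,d_true,e_true stage-2 NPPA coefficients.
#' @param chl_res_sd,par_res_sd,npp_res_sd residual noise SDs (>= 0).
#' @param chl_base,par_base,npp_base positive base fields (scalar or
#'   per-latitude).
#' @param mhw_amp multiplier applied to the SST-coupled NPPA pathway on
#'   cell-months whose SSTA exceeds its own 90th percentile; 1 disables the
#'   conditional amplification. Values > 1 emulate a regime in which extreme
#'   warmth tightens the NPP-SST coupling.
#' @param use_vgpm_forward if `TRUE`, NPP is generated through
#'   [vgpm_eppley_forward()] applied to the simulated CHL/SST/PAR instead of
#'   the linear combination; the truth record then carries only the CHL/PAR
#'   coefficients.
#' @param vgpm parameters for the forward model (a [vgpm_params()] object).
#' @param seed integer seed; identical seeds give bit-identical scenes.
#'
#' @return A validated list of class `scene_config`.
#' @export
scene_config <- function(n_years = 21, n_lat = 10, n_lon = 10,
                         lat = NULL, lon = NULL, start_year = 1998,
                         sst_mean = NULL, sst_seasonal_amp = NULL,
                         ar1_phi = 0.5, sst_noise_sd = 0.8, mhw_boost = 0,
                         alpha_true = -0.05, beta_true = 0.8,
                         a_true = 15, b_true = 450, c_true = 4,
                         d_true = 450, e_true = 4,
                         chl_res_sd = 0.08, par_res_sd = 2.5,
                         npp_res_sd = 40,
                         chl_base = 0.6, par_base = 35, npp_base = 600,
                         mhw_amp = 1, use_vgpm_forward = FALSE,
                         vgpm = vgpm_params(), seed = 1L) {
  if (is.null(lat)) lat <- seq(-80, 80, length.out = n_lat)
  if (is.null(lon)) lon <- seq(0, 360 - 360 / n_lon, length.out = n_lon)
  n_lat <- length(lat); n_lon <- length(lon)
  latr <- lat * pi / 180
  if (is.null(sst_mean)) sst_mean <- -2 + 30 * cos(latr)
  if (is.null(sst_seasonal_amp)) sst_seasonal_amp <- 1 + 4 * abs(sin(latr))
  sst_mean <- rep_len(sst_mean, n_lat)
  sst_seasonal_amp <- rep_len(sst_seasonal_amp, n_lat)
  cfg <- list(n_years = as.integer(n_years), n_lat = n_lat, n_lon = n_lon,
              lat = as.numeric(lat), lon = as.numeric(lon),
              start_year = as.integer(start_year),
              sst_mean = sst_mean, sst_seasonal_amp = sst_seasonal_amp,
              ar1_phi = ar1_phi, sst_noise_sd = sst_noise_sd,
              mhw_boost = mhw_boost,
              alpha_true = alpha_true, beta_true = beta_true,
              a_true = a_true, b_true = b_true, c_true = c_true,
              d_true = d_true, e_true = e_true,
              chl_res_sd = chl_res_sd, par_res_sd = par_res_sd,
              npp_res_sd = npp_res_sd,
              chl_base = rep_len(chl_base, n_lat),
              par_base = rep_len(par_base, n_lat),
              npp_base = rep_len(npp_base, n_lat),
              mhw_amp = mhw_amp,
              use_vgpm_forward = isTRUE(use_vgpm_forward),
              vgpm = vgpm, seed = as.integer(seed))
  num <- cfg[c("sst_mean", "sst_seasonal_amp", "ar1_phi", "sst_noise_sd",
               "mhw_boost", "alpha_true", "beta_true", "a_true", "b_true",
               "c_true", "d_true", "e_true", "chl_res_sd", "par_res_sd",
               "npp_res_sd", "chl_base", "par_base", "npp_base", "mhw_amp")]
  if (!all(vapply(num, function(v) all(is.finite(v)), TRUE)))
    stop("non-finite value in scene configuration")
  if (cfg$n_years < 2) stop("n_years must be >= 2")
  if (n_lat * n_lon < 2) stop("grid too small: need at least 2 cells")
  if (abs(cfg$ar1_phi) >= 1) stop("|ar1_phi| must be < 1")
  if (any(c(cfg$sst_noise_sd, cfg$chl_res_sd, cfg$par_res_sd,
            cfg$npp_res_sd, cfg$mhw_boost) < 0))
    stop("noise SDs and mhw_boost must be >= 0")
  if (any(lat < -90 | lat > 90)) stop("lat must lie within [-90, 90]")
  if (cfg$mhw_amp <= 0) stop("mhw_amp must be positive")
  class(cfg) <- "scene_config"
  cfg
}

#' Scene with an MHW-conditional regime shift in NPP drivers
#'
#' A [scene_config()] preset for demonstrating the dominance regime shift: the
#' SST-coupled NPPA pathway is amplified by 1.5 on each cell's extreme-warm
#' months, and the coupling-to-noise ratio is set so that under moderate warm
#' months the SST-dependent composite sits near the residual-composite
#' magnitude (dominance is contested) while MHW-month composites, which
#' condition on large SSTA, tip it toward SST dependence. See the methods
#' vignette for the design analysis behind these values.
#'
#' @param seed integer seed.
#' @param n_lat,n_lon grid size (default 20 x 20).
#' @param ... further overrides passed to [scene_config()].
#' @return A `scene_config`.
#' @export
regime_shift_config <- function(seed = 1L, n_lat = 20, n_lon = 20, ...) {
  scene_config(n_lat = n_lat, n_lon = n_lon, seed = seed,
               a_true = 25, npp_res_sd = 80, mhw_amp = 1.5, ...)
}

# AR(1) series per cell from a matrix of innovations [time, cell], started at
# the stationary distribution.
ar1_filter <- function(innov, phi, init) {
  x <- matrix(0, nrow(innov), ncol(innov))
  prev <- init
  for (t in seq_len(nrow(innov))) {
    prev <- phi * prev + innov[t, ]
    x[t, ] <- prev
  }
  x
}

#' Simulate a monthly gridded ocean scene with known truth
#'
#' Draws SST, CHL, PAR and NPP fields under the forward model described in
#' [scene_config()]. The returned `truth` record carries the generating
#' coefficients, the latent anomaly/noise series, and the fraction of
#' cell-months clipped at zero to keep CHL/PAR/NPP physical (small under the
#' defaults, where base fields dwarf the anomalies).
#'
#' @param cfg a [scene_config()].
#' @return A list with elements `sst`, `chl`, `par`, `npp` (each a
#'   [gridded_series()]) and `truth` (coefficients, clip fractions, latent
#'   series, and the config).
#' @export
simulate_scene <- function(cfg) {
  if (!inherits(cfg, "scene_config")) stop("`cfg` must be a scene_config")
  set.seed(cfg$seed)
  nt <- cfg$n_years * 12L
  nc <- cfg$n_lat * cfg$n_lon
  months <- rep(1:12, cfg$n_years)
  years <- cfg$start_year + rep(seq_len(cfg$n_years) - 1L, each = 12L)

  # innovations, optionally with a fattened warm tail (stationary, recentred)
  innov <- matrix(stats::rnorm(nt * nc, sd = cfg$sst_noise_sd), nt, nc)
  if (cfg$mhw_boost > 0) {
    p_bump <- 0.05
    bump <- matrix(stats::rexp(nt * nc, rate = 1 / cfg$mhw_boost) *
                     (stats::runif(nt * nc) < p_bump), nt, nc)
    innov <- innov + bump - p_bump * cfg$mhw_boost
  }
  init_sd <- if (cfg$sst_noise_sd > 0) cfg$sst_noise_sd / sqrt(1 - cfg$ar1_phi^2) else 0
  init <- stats::rnorm(nc, sd = init_sd)
  ssta <- ar1_filter(innov, cfg$ar1_phi, init)

  eps_chl <- matrix(stats::rnorm(nt * nc, sd = cfg$chl_res_sd), nt, nc)
  eps_par <- matrix(stats::rnorm(nt * nc, sd = cfg$par_res_sd), nt, nc)
  eps_npp <- matrix(stats::rnorm(nt * nc, sd = cfg$npp_res_sd), nt, nc)

  chla <- cfg$alpha_true * ssta + eps_chl
  para <- cfg$beta_true * ssta + eps_par

  sst_coupled <- (cfg$a_true + cfg$b_true * cfg$alpha_true +
                    cfg$c_true * cfg$beta_true) * ssta
  if (cfg$mhw_amp != 1) {
    # amplify the SST-coupled pathway on each cell's own extreme-warm months
    q90 <- apply(ssta, 2, stats::quantile, probs = 0.9, type = 7)
    hot <- sweep(ssta, 2, q90, ">")
    sst_coupled <- sst_coupled * ifelse(hot, cfg$mhw_amp, 1)
  }
  nppa <- sst_coupled + cfg$d_true * eps_chl + cfg$e_true * eps_par + eps_npp

  # seasonal SST cycle: austral/boreal summer peaks (Feb south, Aug north)
  peak <- ifelse(cfg$lat >= 0, 8, 2)
  cyc <- outer(months, seq_len(cfg$n_lat),
               function(m, i) cfg$sst_seasonal_amp[i] *
                 cos(2 * pi * (m - peak[i]) / 12))
  sst_base <- cyc + matrix(cfg$sst_mean, nt, cfg$n_lat, byrow = TRUE)
  sst_base_full <- sst_base[, rep(seq_len(cfg$n_lat), times = cfg$n_lon)]

  lat_of_cell <- rep(seq_len(cfg$n_lat), times = cfg$n_lon)
  base_of <- function(b) matrix(b[lat_of_cell], nt, nc, byrow = TRUE)

  sst <- sst_base_full + ssta
  chl <- base_of(cfg$chl_base) + chla
  par <- base_of(cfg$par_base) + para
  clip <- function(x) {
    frac <- mean(x < 0)
    x[x < 0] <- 0
    list(x = x, frac = frac)
  }
  chl_c <- clip(chl); par_c <- clip(par)

  if (cfg$use_vgpm_forward) {
    npp <- vgpm_eppley_forward(chl_c$x, sst, par_c$x, cfg$vgpm)
    npp_c <- list(x = npp, frac = 0)
  } else {
    npp_c <- clip(base_of(cfg$npp_base) + nppa)
  }

  to_gs <- function(m, units) {
    a <- array(m, dim = c(nt, cfg$n_lat, cfg$n_lon))
    gridded_series(a, years, months, cfg$lat, cfg$lon, units)
  }
  truth <- list(
    alpha = cfg$alpha_true, beta = cfg$beta_true,
    a = if (cfg$use_vgpm_forward) NA_real_ else cfg$a_true,
    b = if (cfg$use_vgpm_forward) NA_real_ else cfg$b_true,
    c = if (cfg$use_vgpm_forward) NA_real_ else cfg$c_true,
    d = if (cfg$use_vgpm_forward) NA_real_ else cfg$d_true,
    e = if (cfg$use_vgpm_forward) NA_real_ else cfg$e_true,
    clip_frac = c(chl = chl_c$frac, par = par_c$frac, npp = npp_c$frac),
    latent = list(ssta = ssta, eps_chl = eps_chl, eps_par = eps_par,
                  eps_npp = eps_npp),
    config = cfg)
  list(sst = to_gs(sst, "degC"),
       chl = to_gs(chl_c$x, "mg m-3"),
       par = to_gs(par_c$x, "mol photons m-2 day-1"),
       npp = to_gs(npp_c$x, "mg C m-2 day-1"),
       truth = truth)
}
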