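#' Parameters of the Eppley-VGPM forward model
#'
#' The Vertically Generalized Production Model estimates depth-integrated NPP
#' from surface chlorophyll, SST, PAR and day length. In the Eppley variant
#' the chlorophyll-specific optimal rate \eqn{P^B_{opt}} increases
#' exponentially with SST instead of peaking near 20 degC:
#' \deqn{P^B_{opt}(T) = s \cdot 10^{(k T + c)}}
#' The defaults follow the published model conventions: `pbopt_scale = 1.54`,
#' `pbopt_exp = 0.0275`, `pbopt_offset = -0.07` (mg C (mg chl)^-1 h^-1), a
#' hyperbolic light term saturating at `par_sat = 4.1` mol photons m^-2 d^-1,
#' Morel-Berthon euphotic depth from column-integrated chlorophyll, 12 h day
#' length, and the 0.66125 structural scale factor. Every coefficient is
#' configurable; only the structural form matters for pipeline testing.
#'
#' @param pbopt_scale,pbopt_exp,pbopt_offset coefficients of the exponential
#'   \eqn{P^B_{opt}} (scale > 0).
#' @param par_sat light half-saturation constant (mol photons m^-2 d^-1).
#' @param zeu_low_scale,zeu_low_exp column chlorophyll coefficients for
#'   CHL < 1 mg m^-3 (`Ctot = zeu_low_scale * CHL^zeu_low_exp`).
#' @param zeu_high_scale,zeu_high_exp same for CHL >= 1 mg m^-3.
#' @param day_length photoperiod in hours.
#' @param scale overall structural scale factor.
#'
#' @return A list of class `vgpm_params`.
#' @export
vgpm_params <- function(pbopt_scale = 1.54, pbopt_exp = 0.0275,
                        pbopt_offset = -0.07, par_sat = 4.1,
                        zeu_low_scale = 38.0, zeu_low_exp = 0.425,
                        zeu_high_scale = 40.2, zeu_high_exp = 0.507,
                        day_length = 12, scale = 0.66125) {
  p <- list(pbopt_scale = pbopt_scale, pbopt_exp = pbopt_exp,
            pbopt_offset = pbopt_offset, par_sat = par_sat,
            zeu_low_scale = zeu_low_scale, zeu_low_exp = zeu_low_exp,
            zeu_high_scale = zeu_high_scale, zeu_high_exp = zeu_high_exp,
            day_length = day_length, scale = scale)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v), TRUE)))
    stop("all VGPM parameters must be finite scalars")
  if (pbopt_scale <= 0 || par_sat <= 0 || day_length <= 0 || scale <= 0)
    stop("pbopt_scale, par_sat, day_length and scale must be positive")
  class(p) <- "vgpm_params"
  p
}

#' Eppley-VGPM forward NPP
#'
#' Computes depth-integrated net primary production
#' \deqn{NPP = scale \cdot P^B_{opt}(SST) \cdot \frac{PAR}{PAR + k_{sat}}
#'   \cdot Z_{eu}(CHL) \cdot CHL \cdot D}
#' with \eqn{P^B_{opt}} exponential in SST, a saturating light term, and
#' euphotic depth \eqn{Z_{eu}} derived from column-integrated chlorophyll
#' (Morel-Berthon case-1 relations). Zero chlorophyll yields exactly zero NPP.
#' Because the SST dependence is exponential, `npp(T + d) / npp(T)` at fixed
#' CHL and PAR does not depend on `T`.
#'
#' @param chl chlorophyll (mg m^-3), >= 0.
#' @param sst sea surface temperature (degC).
#' @param par photosynthetically active radiation (mol photons m^-2 d^-1),
#'   >= 0.
#' @param params a [vgpm_params()] object.
#' @return NPP in mg C m^-2 day^-1, same shape as the inputs. `NA` inputs
#'   propagate.
#' @export
vgpm_eppley_forward <- function(chl, sst, par, params = vgpm_params()) {
  if (!inherits(params, "vgpm_params")) stop("`params` must be a vgpm_params object")
  if (any(chl < 0, na.rm = TRUE)) stop("negative CHL rejected")
  if (any(par < 0, na.rm = TRUE)) stop("negative PAR rejected")
  pbopt <- params$pbopt_scale *
    10^(params$pbopt_exp * sst + params$pbopt_offset)
  light <- par / (par + params$par_sat)
  # column-integrated chlorophyll -> euphotic depth; the low-CHL branch
  # applies strictly below 1 mg m^-3
  ctot <- ifelse(chl < 1,
                 params$zeu_low_scale * chl^params$zeu_low_exp,
                 params$zeu_high_scale * chl^params$zeu_high_exp)
  zeu <- 568.2 * ctot^(-0.746)
  zeu <- ifelse(zeu > 102, 200 * ctot^(-0.293), zeu)
  npp <- params$scale * pbopt * light * zeu * chl * params$day_length
  # chl == 0 makes zeu infinite but biomass zero: production is exactly 0
  npp[!is.na(chl) & chl == 0] <- 0
  npp
}
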