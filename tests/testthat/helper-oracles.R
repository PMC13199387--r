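# Independent oracles and small constructors used across the suite.

# Closed-form normal-equations decomposition: stage-1 slopes by explicit
# Gram solve, stage-2 on the identifiable design with the b = d, c = e
# allocation. Shares no code path with decompose_cell().
oracle_decompose <- function(ssta, chla, para, nppa) {
  alpha <- sum(ssta * chla) / sum(ssta^2)
  beta <- sum(ssta * para) / sum(ssta^2)
  ch_res <- chla - alpha * ssta
  pa_res <- para - beta * ssta
  X <- cbind(ssta, ch_res, pa_res)
  theta <- solve(crossprod(X), crossprod(X, nppa))
  d <- theta[2]; e <- theta[3]
  c(alpha = alpha, beta = beta,
    a = theta[1] - d * alpha - e * beta, b = d, c = e, d = d, e = e)
}

# A single synthetic cell drawn directly from the anomaly model (no grid, no
# climatology round trip): SSTA iid or AR(1), residuals iid normal.
make_cell <- function(n, seed, alpha = -0.05, beta = 0.8, a = 15, b = 450,
                      cc = 4, d = 450, e = 4, sd_sst = 0.9, phi = 0,
                      sd_chl = 0.08, sd_par = 2.5, sd_npp = 40) {
  set.seed(seed)
  innov <- rnorm(n, sd = sd_sst)
  ssta <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  eps_chl <- rnorm(n, sd = sd_chl)
  eps_par <- rnorm(n, sd = sd_par)
  eps_npp <- rnorm(n, sd = sd_npp)
  list(ssta = ssta,
       chla = alpha * ssta + eps_chl,
       para = beta * ssta + eps_par,
       nppa = (a + b * alpha + cc * beta) * ssta +
         d * eps_chl + e * eps_par + eps_npp,
       truth = c(alpha = alpha, beta = beta, a = a, b = b, c = cc,
                 d = d, e = e))
}

# Wrap a [time, cell] matrix (or vector) as a gridded_series on a trivial
# grid; cells are laid out along longitude at the given latitude(s).
as_gs <- function(m, lat = 0, units = "unit", start_year = 2000) {
  if (is.vector(m)) m <- matrix(m, ncol = 1)
  nt <- nrow(m); nc <- ncol(m)
  nlat <- length(lat)
  stopifnot(nc %% nlat == 0)
  nlon <- nc / nlat
  gridded_series(array(m, c(nt, nlat, nlon)),
                 years = start_year + (seq_len(nt) - 1) %/% 12,
                 months = (seq_len(nt) - 1) %% 12 + 1,
                 lat = lat, lon = seq(0, 359, length.out = nlon),
                 units = units)
}

# Vector with an exact given sample correlation to x (up to sign of r).
with_exact_cor <- function(x, r, seed = 1) {
  set.seed(seed)
  z <- rnorm(length(x))
  ex <- x - mean(x)
  ez <- z - mean(z)
  ez <- ez - sum(ez * ex) / sum(ex^2) * ex  # orthogonal to centered x
  y <- r * ex / sqrt(sum(ex^2)) + sqrt(1 - r^2) * ez / sqrt(sum(ez^2))
  y
}
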