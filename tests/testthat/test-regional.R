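simple_labels <- function(lab_vec, nlat = 1, nlon = 1) {
  nt <- length(lab_vec)
  structure(list(label = array(rep(lab_vec, nlat * nlon), c(nt, nlat, nlon)),
                 codes = c(OTHER = 0L, SSTA_PLUS = 1L, MHW = 2L),
                 years = 2000 + (seq_len(nt) - 1) %/% 12,
                 months = (seq_len(nt) - 1) %% 12 + 1,
                 lat = seq(0, length.out = nlat, by = 10),
                 lon = seq(0, length.out = nlon, by = 10)),
            class = "condition_labels")
}

test_that("change ratio is the percent departure of the condition mean", {
  lab <- simple_labels(c(rep(2L, 6), rep(0L, 30)))
  x <- c(rep(120, 6), rep(96, 30))   # condition mean 120, long-term mean 100
  cr <- change_ratio(as_gs(x), lab, "MHW")
  expect_equal(cr[1, 1], 20)
  cr0 <- change_ratio(as_gs(rep(50, 36)), lab, "MHW")
  expect_equal(cr0[1, 1], 0)
})

test_that("change ratio masks starved cells and near-zero denominators", {
  lab <- simple_labels(c(2L, 2L, rep(0L, 34)))
  x <- rnorm(36) + 100
  expect_true(is.na(change_ratio(as_gs(x), lab, "MHW")[1, 1]))  # 2 < 3 months
  lab2 <- simple_labels(c(rep(2L, 5), rep(0L, 31)))
  y <- c(rep(1, 5), rep(-5 / 31, 31))  # long-term mean ~ 0
  cr <- change_ratio(as_gs(y), lab2, "MHW", denom_floor = 1e-3)
  expect_true(is.na(cr[1, 1]))
  expect_identical(attr(cr, "n_floor_masked"), 1L)
})

test_that("change ratio is invariant to unit rescaling", {
  set.seed(2)
  lab <- simple_labels(sample(0:2, 48, replace = TRUE))
  x <- rlnorm(48, meanlog = 4)
  a <- change_ratio(as_gs(x), lab, "SSTA_PLUS")
  b <- change_ratio(as_gs(x * 1000), lab, "SSTA_PLUS")
  expect_equal(a[1, 1], b[1, 1], tolerance = 1e-12)
})

test_that("regional summaries: constant fields, quantile oracle, weighted mean", {
  lat <- c(0, 60)
  msk <- region_mask("box", matrix(TRUE, 2, 3), lat)
  s <- regional_summary(matrix(5, 2, 3), msk)
  expect_equal(s$weighted_mean, 5)
  expect_equal(c(s$q1, s$median, s$q3), c(5, 5, 5))
  expect_equal(s$whisker_lo, 5)
  # {1..5} at equal latitude: type-7 quartiles by sort-and-interpolate
  m5 <- region_mask("five", matrix(TRUE, 1, 5), 0)
  s5 <- regional_summary(matrix(1:5, 1, 5), m5)
  expect_equal(s5$median, 3)
  expect_equal(s5$q1, quantile(1:5, 0.25, type = 7, names = FALSE))
  expect_equal(s5$q3, quantile(1:5, 0.75, type = 7, names = FALSE))
  expect_true(s5$q1 <= s5$median && s5$median <= s5$q3)
  # two cells at lat 0 and 60: cos weights 1 and 0.5
  m2 <- region_mask("pair", matrix(TRUE, 2, 1), lat)
  s2 <- regional_summary(matrix(c(0, 10), 2, 1), m2)
  expect_equal(s2$weighted_mean, 10 / 3)
})

test_that("whiskers are clipped to the observed range and NA cells drop out", {
  m <- region_mask("r", matrix(TRUE, 1, 9), 0)
  x <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 100), 1, 9)
  s <- regional_summary(x, m)
  expect_equal(s$whisker_lo, 1)        # Q1 - 1.5 IQR < min
  expect_lt(s$whisker_hi, 100)         # the outlier is outside the fence
  x[1, 5] <- NA
  expect_equal(regional_summary(x, m)$n_cells, 8L)
  empty <- matrix(NA_real_, 1, 9)
  expect_error(regional_summary(empty, m), "empty")
  expect_error(region_mask("none", matrix(FALSE, 2, 2), c(0, 1)), "no TRUE")
})

test_that("band means honor edges and aggregate exactly to the global mean", {
  lat <- seq(-79, 79, by = 2)
  nlon <- 6
  f7 <- matrix(7, length(lat), nlon)
  bs <- band_summary(f7, lat, c(-80, -45, 45, 80))
  expect_equal(bs$weighted_mean, rep(7, 3))
  # indicator aligned with the membership rule (lower edge inclusive)
  ind <- matrix(ifelse(lat < -45 | lat >= 45, 1, -1), length(lat), nlon)
  bs2 <- band_summary(ind, lat, c(-80, -45, 45, 80))
  expect_equal(bs2$weighted_mean, c(1, -1, 1))
  set.seed(77)
  r <- matrix(rnorm(length(lat) * nlon), length(lat), nlon)
  bs3 <- band_summary(r, lat, c(-80, -45, 0, 45, 80))
  grand <- sum(bs3$weighted_mean * bs3$weight) / sum(bs3$weight)
  w <- matrix(cos(lat * pi / 180), length(lat), nlon)
  expect_equal(grand, sum(w * r) / sum(w), tolerance = 1e-12)
  # membership is lower-edge inclusive
  one <- band_summary(matrix(1, 2, 1), c(-45, 45), c(-45, 45, 80))
  expect_identical(one$n_cells, c(1L, 1L))
  expect_error(band_summary(f7, lat, c(10, 10)), "increasing")
})

test_that("class-conditioned summaries contrast the two response classes", {
  cls <- structure(list(class = matrix(c("ENHANCED", "ENHANCED",
                                         "INHIBITED", "NEUTRAL"), 2, 2),
                        lat = c(0, 30), lon = c(0, 10),
                        r = NULL, p = NULL, n = NULL, alpha_sig = 0.1),
                   class = "response_class_map")
  baseline <- matrix(c(1, 1, -1, 99), 2, 2)
  anom <- matrix(c(4, 4, -6, 0), 2, 2)
  s <- class_conditioned_summary(baseline, anom, cls)
  en_b <- s[s$class == "ENHANCED" & s$field == "baseline", ]
  in_a <- s[s$class == "INHIBITED" & s$field == "anomaly", ]
  expect_equal(en_b$weighted_mean, 1)
  expect_equal(in_a$weighted_mean, -6)
  # neutral cells never contaminate a class summary
  expect_true(all(s$weighted_mean != 99))
  cls$class[cls$class == "INHIBITED"] <- "NEUTRAL"
  expect_error(class_conditioned_summary(baseline, anom, cls), "empty")
})

test_that("unit conversion to gC m-2 year-1 is the 365/1000 scale", {
  expect_equal(mgc_day_to_gc_year(1000), 365)
  expect_equal(mgc_day_to_gc_year(c(0, -10)), c(0, -3.65))
})
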