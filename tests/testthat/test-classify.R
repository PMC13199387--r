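make_comp <- function(dep, indep, lat) {
  structure(list(nppa = dep + indep, sst_dependent = dep,
                 sst_independent = indep,
                 n_months = matrix(10L, nrow(dep), ncol(dep)),
                 condition = "MHW", lat = lat,
                 lon = seq_len(ncol(dep))),
            class = "component_composite")
}

test_that("dominance compares absolute composite magnitudes with the tie rule", {
  dep <- matrix(c(3, 1, NA, 0.5), 2, 2)
  indep <- matrix(c(-1, -1, 2, NA), 2, 2)
  dm <- dominance_map(make_comp(dep, indep, lat = c(0, 45)))
  expect_identical(dm$class[1, 1], "SST_DEPENDENT")    # |3| > |-1|
  expect_identical(dm$class[2, 1], "SST_INDEPENDENT")  # exact tie
  expect_true(dm$tie[2, 1])
  expect_identical(dm$class[1, 2], "UNDEFINED")
  expect_identical(dm$class[2, 2], "UNDEFINED")
})

test_that("dominance and area fractions are invariant to positive rescaling", {
  set.seed(41)
  dep <- matrix(rnorm(100), 10, 10)
  indep <- matrix(rnorm(100), 10, 10)
  lat <- seq(-60, 60, length.out = 10)
  d1 <- dominance_map(make_comp(dep, indep, lat))
  d2 <- dominance_map(make_comp(7 * dep, 7 * indep, lat))
  expect_identical(d1$class, d2$class)
  expect_equal(area_fraction(d1, "SST_DEPENDENT"),
               area_fraction(d2, "SST_DEPENDENT"))
})

test_that("perfect coupling is ENHANCED with r = 1", {
  set.seed(7)
  ssta <- as_gs(rnorm(24))
  nppa <- as_gs(2 * ssta$values[, 1, 1])
  rc <- response_class_map(nppa, ssta)
  expect_equal(rc$r[1, 1], 1)
  expect_identical(rc$class[1, 1], "ENHANCED")
  rc2 <- response_class_map(as_gs(-2 * ssta$values[, 1, 1]), ssta)
  expect_identical(rc2$class[1, 1], "INHIBITED")
})

test_that("the class boundary sits at the t critical value for df = n - 2", {
  n <- 24; df <- n - 2
  tcrit <- qt(0.95, df)
  rcrit <- tcrit / sqrt(tcrit^2 + df)  # two-sided p = 0.10 exactly here
  set.seed(5)
  x <- rnorm(n)
  for (delta in c(1e-6, -1e-6)) {
    y <- with_exact_cor(x, rcrit + delta)
    rc <- response_class_map(as_gs(y), as_gs(x))
    expect_equal(rc$r[1, 1], rcrit + delta, tolerance = 1e-9)
    expect_identical(rc$class[1, 1],
                     if (delta > 0) "ENHANCED" else "NEUTRAL")
  }
})

test_that("type-I error of the response classifier matches alpha_sig", {
  set.seed(101)
  n <- 24; ncell <- 2500
  ssta <- as_gs(matrix(rnorm(n * ncell), n, ncell), lat = rep(0, 50))
  nppa <- as_gs(matrix(rnorm(n * ncell), n, ncell), lat = rep(0, 50))
  rc <- response_class_map(nppa, ssta, alpha_sig = 0.10)
  rate <- mean(rc$class != "NEUTRAL")
  expect_lt(abs(rate - 0.10), 1.96 * sqrt(0.1 * 0.9 / ncell))
})

test_that("degenerate or short samples are UNDEFINED; alpha_sig = 1 classifies everything", {
  ssta <- as_gs(cbind(rnorm(24), rep(1, 24)), lat = c(0, 10))
  nppa <- as_gs(cbind(rnorm(24), rnorm(24)), lat = c(0, 10))
  rc <- response_class_map(nppa, ssta)
  expect_identical(rc$class[2, 1], "UNDEFINED")   # zero-variance SSTA
  short <- as_gs(rbind(matrix(NA_real_, 20, 1), matrix(rnorm(4), 4, 1)))
  rc2 <- response_class_map(short, as_gs(rnorm(24)))
  expect_identical(rc2$class[1, 1], "UNDEFINED")  # n < min_n
  rc3 <- response_class_map(nppa, ssta, alpha_sig = 1)
  expect_identical(rc3$class[1, 1] %in% c("ENHANCED", "INHIBITED"), TRUE)
})

test_that("condition-restricted correlation uses only the condition months", {
  nt <- 48
  set.seed(3)
  x <- rnorm(nt)
  y <- numeric(nt)
  lab <- array(0L, c(nt, 1, 1))
  lab[1:24, 1, 1] <- 2L
  y[1:24] <- 3 * x[1:24]            # perfectly coupled during MHW months
  y[25:48] <- -3 * x[25:48]         # anti-coupled otherwise
  labels <- structure(list(label = lab,
                           codes = c(OTHER = 0L, SSTA_PLUS = 1L, MHW = 2L),
                           years = 2000 + (seq_len(nt) - 1) %/% 12,
                           months = (seq_len(nt) - 1) %% 12 + 1,
                           lat = 0, lon = 0),
                      class = "condition_labels")
  rc <- response_class_map(as_gs(y), as_gs(x), labels = labels,
                           condition = "MHW")
  expect_equal(rc$r[1, 1], 1)
  expect_identical(rc$n[1, 1], 24)
})

test_that("area fractions use cos-latitude weights and partition to one", {
  cls <- matrix(c("X", "X", "Y", "Y"), 2, 2)       # rows: lat 0 and 60
  lat <- c(0, 60)
  cls <- matrix(c("X", "Y", "X", "Y"), 2, 2)       # lat 0 -> X, lat 60 -> Y
  expect_equal(area_fraction(cls, "X", lat), 2 / 3)  # (2*1)/(2*1 + 2*0.5)
  expect_equal(area_fraction(cls, "Y", lat), 1 / 3)
  expect_equal(area_fraction(matrix("Z", 3, 3), "Z", c(-10, 0, 10)), 1)
  cls2 <- matrix(c("A", "UNDEFINED", NA, "B"), 2, 2)
  expect_equal(area_fraction(cls2, "A", c(0, 0)) +
                 area_fraction(cls2, "B", c(0, 0)), 1)
  expect_error(area_fraction(matrix("UNDEFINED", 2, 2), "A", c(0, 0)),
               "no defined cells")
})

test_that("random class assignment recovers its probability", {
  set.seed(55)
  ncell <- 10000
  cls <- matrix(ifelse(runif(ncell) < 0.3, "HOT", "COLD"), 100, 100)
  f <- area_fraction(cls, "HOT", rep(0, 100))
  expect_lt(abs(f - 0.3), 3 * sqrt(0.3 * 0.7 / ncell))
})

test_that("variance-share dominance uses the within-condition variances", {
  comp <- make_comp(matrix(10, 2, 2), matrix(-0.1, 2, 2), lat = c(0, 30))
  comp$sst_dependent_var <- matrix(1, 2, 2)
  comp$sst_independent_var <- matrix(5, 2, 2)
  dm_mean <- dominance_map(comp)                       # |10| > |-0.1|
  dm_var <- dominance_map(comp, metric = "variance")   # 1 < 5
  expect_true(all(dm_mean$class == "SST_DEPENDENT"))
  expect_true(all(dm_var$class == "SST_INDEPENDENT"))
})

test_that("the effective-df correction deflates significance on autocorrelated series", {
  set.seed(61)
  n <- 120; ncell <- 400
  ar <- function() {
    m <- matrix(rnorm(n * ncell), n, ncell)
    apply(m, 2, function(x) as.numeric(stats::filter(x, 0.7, method = "recursive")))
  }
  ssta <- as_gs(ar(), lat = rep(0, 20))
  nppa <- as_gs(ar(), lat = rep(0, 20))
  plain <- response_class_map(nppa, ssta, alpha_sig = 0.10)
  corr <- response_class_map(nppa, ssta, alpha_sig = 0.10,
                             effective_df = TRUE)
  rate_plain <- mean(plain$class != "NEUTRAL")
  rate_corr <- mean(corr$class != "NEUTRAL")
  expect_lt(rate_corr, rate_plain)  # shared persistence inflates the plain test
  expect_true(all(corr$p >= plain$p - 1e-12))
})
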