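test_that("zero-noise cells are recovered exactly with the stated conventions", {
  set.seed(31)
  ssta <- rnorm(120)
  chla <- 2 * ssta
  para <- -1 * ssta
  nppa <- 3 * ssta + 1 * chla + (-2) * para  # residual pathways are zero
  cd <- decompose_cell(ssta, chla, para, nppa)
  expect_equal(cd$alpha, 2, tolerance = 1e-12)
  expect_equal(cd$beta, -1, tolerance = 1e-12)
  # residual regressors are identically zero: d and e are dropped to 0 and
  # the whole SSTA slope (3 + 1*2 + (-2)*(-1) = 7) lands on `a`
  expect_equal(cd$d, 0)
  expect_equal(cd$e, 0)
  expect_equal(cd$a, 7, tolerance = 1e-10)
  expect_true(any(grepl("dropped_", cd$flags)))
  dep <- cd$terms$a_ssta + cd$terms$b_chla_sst + cd$terms$c_para_sst
  expect_equal(dep, nppa, tolerance = 1e-10)
  expect_lt(max(abs(cd$terms$nppa_res)), 1e-10 * max(abs(nppa)))
})

test_that("the six terms always sum to NPPA and residuals are orthogonal", {
  for (seed in c(3, 17)) {
    cell <- make_cell(252, seed, phi = 0.4)
    cd <- decompose_cell(cell$ssta, cell$chla, cell$para, cell$nppa)
    six <- Reduce(`+`, cd$terms)
    expect_lt(max(abs(cell$nppa - six)), 1e-10 * max(abs(cell$nppa)))
    expect_equal(cell$nppa, cd$sst_dependent + cd$sst_independent,
                 tolerance = 1e-10)
    # stage-1 residuals orthogonal to SSTA under the no-intercept fit
    # (uncentered correlation); stage-2 residual orthogonal to the design
    s <- cell$ssta
    ucor <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    expect_lt(abs(ucor(cd$chla_res, s)), 1e-8)
    expect_lt(abs(ucor(cd$para_res, s)), 1e-8)
    r <- cd$terms$nppa_res
    for (x in list(s, cd$chla_res, cd$para_res))
      expect_lt(abs(sum(r * x)) / (sd(r) * sd(x) * length(r)), 1e-8)
  }
})

test_that("coefficients match the independent normal-equations oracle", {
  cell <- make_cell(252, 3)
  cd <- decompose_cell(cell$ssta, cell$chla, cell$para, cell$nppa)
  or <- oracle_decompose(cell$ssta, cell$chla, cell$para, cell$nppa)
  got <- c(alpha = cd$alpha, beta = cd$beta, a = cd$a, b = cd$b,
           c = cd$c, d = cd$d, e = cd$e)
  expect_equal(got, or, tolerance = 1e-8)
})

test_that("scale equivariance: scaling NPPA scales a-e and all six terms", {
  cell <- make_cell(200, 8)
  cd1 <- decompose_cell(cell$ssta, cell$chla, cell$para, cell$nppa)
  cd2 <- decompose_cell(cell$ssta, cell$chla, cell$para, 10 * cell$nppa)
  for (nm in c("a", "b", "c", "d", "e"))
    expect_equal(cd2[[nm]], 10 * cd1[[nm]], tolerance = 1e-10)
  expect_equal(cd2$sst_dependent, 10 * cd1$sst_dependent, tolerance = 1e-10)
  expect_equal(cd2$alpha, cd1$alpha)  # stage 1 untouched
})

test_that("degenerate SSTA gives the zero-coefficient convention with conservation", {
  set.seed(9)
  n <- 60
  chla <- rnorm(n); para <- rnorm(n); nppa <- 2 * chla + rnorm(n)
  cd <- decompose_cell(rep(0, n), chla, para, nppa, min_n = 24)
  expect_true("degenerate_sst" %in% cd$flags)
  expect_identical(c(cd$alpha, cd$beta, cd$a), c(0, 0, 0))
  expect_equal(Reduce(`+`, cd$terms), nppa, tolerance = 1e-10)
  # the residual pathways still carry signal
  expect_equal(cd$d, 2, tolerance = 0.5)
})

test_that("minimum-sample rule masks short cells; listwise deletion shares one sample", {
  cell <- make_cell(30, 12)
  cd <- decompose_cell(cell$ssta, cell$chla, cell$para, cell$nppa, min_n = 40)
  expect_false(cd$ok)
  expect_identical(cd$flags, "insufficient_sample")
  expect_true(is.na(cd$alpha))
  # missing months in any series are dropped from all fitted quantities
  chla <- cell$chla; chla[5] <- NA
  cd2 <- decompose_cell(cell$ssta, chla, cell$para, cell$nppa, min_n = 24)
  expect_identical(cd2$n, 29L)
  expect_true(is.na(cd2$terms$nppa_res[5]))
  keep <- setdiff(seq_len(30), 5)
  or <- oracle_decompose(cell$ssta[keep], chla[keep], cell$para[keep],
                         cell$nppa[keep])
  expect_equal(cd2$alpha, or[["alpha"]], tolerance = 1e-10)
})

test_that("optional intercepts are estimated near zero on anomaly input and conserve the budget", {
  cell <- make_cell(252, 21)
  cd <- decompose_cell(cell$ssta, cell$chla, cell$para, cell$nppa,
                       intercept = TRUE)
  # intercepts should be negligible relative to each response's spread
  expect_lt(abs(cd$intercepts[["chl"]]), 0.3 * sd(cell$chla))
  expect_lt(abs(cd$intercepts[["npp"]]), 0.3 * sd(cell$nppa))
  expect_equal(Reduce(`+`, cd$terms), cell$nppa, tolerance = 1e-10)
})

test_that("grid decomposition equals the cell-by-cell answers and isolates missing cells", {
  cell <- make_cell(60, 33)
  m <- cbind(cell$ssta, cell$ssta, cell$ssta, cell$ssta)
  gssta <- as_gs(m, lat = c(0, 30))
  gchla <- as_gs(cbind(cell$chla, cell$chla, cell$chla, cell$chla), lat = c(0, 30))
  gpara <- as_gs(cbind(cell$para, cell$para, cell$para, cell$para), lat = c(0, 30))
  gnppa <- as_gs(cbind(cell$nppa, cell$nppa, cell$nppa, cell$nppa), lat = c(0, 30))
  gd <- decompose_grid(gssta, gchla, gpara, gnppa)
  cd <- decompose_cell(cell$ssta, cell$chla, cell$para, cell$nppa)
  expect_true(all(abs(gd$maps$alpha - cd$alpha) < 1e-12))
  expect_true(all(abs(gd$maps$a - cd$a) < 1e-12))
  # knock out one cell entirely
  gssta2 <- gssta; gssta2$values[, 1, 1] <- NA
  gd2 <- decompose_grid(gssta2, gchla, gpara, gnppa)
  expect_true(is.na(gd2$maps$alpha[1, 1]))
  expect_false(gd2$ok[1, 1])
  expect_equal(gd2$maps$alpha[2, 2], cd$alpha, tolerance = 1e-12)
  expect_identical(gd2$n_masked, 1L)
  expect_error(decompose_grid(gssta2, gchla, gpara, as_gs(m[, 1:2], lat = c(0, 30))),
               "grid|time")
})

test_that("per-cell slope estimates are unbiased on a noisy scene", {
  sc <- simulate_scene(scene_config(n_lat = 10, n_lon = 20, seed = 3))
  cl <- function(x) monthly_climatology(x)
  gd <- decompose_grid(anomalies(sc$sst, cl(sc$sst)),
                       anomalies(sc$chl, cl(sc$chl)),
                       anomalies(sc$par, cl(sc$par)),
                       anomalies(sc$npp, cl(sc$npp)))
  est <- as.vector(gd$maps$alpha)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - sc$truth$alpha), 3 * se)
})

test_that("per-condition refits fit only the subset months", {
  cell <- make_cell(120, 44)
  sub <- rep(c(TRUE, FALSE), 60)
  cd <- decompose_cell(cell$ssta, cell$chla, cell$para, cell$nppa,
                       subset = sub)
  keep <- which(sub)
  or <- oracle_decompose(cell$ssta[keep], cell$chla[keep], cell$para[keep],
                         cell$nppa[keep])
  expect_equal(cd$alpha, or[["alpha"]], tolerance = 1e-10)
  expect_equal(cd$d, or[["d"]], tolerance = 1e-10)
  expect_identical(cd$n, 60L)
  expect_true(all(is.na(cd$sst_dependent[!sub])))
})
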