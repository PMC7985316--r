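# Inverse problem: fit window, single-wavelength fits, spectra.

test_that("fit_window applies the 80%/1% thresholds", {
  counts <- c(0, 100, 800, 1000, 600, 300, 50, 9, 0)
  expect_equal(unname(fit_window(counts)), c(3, 7))
  # thresholds are relative: scaling leaves the window unchanged
  expect_equal(fit_window(counts * 7), fit_window(counts))
  # symmetric triangle
  tri <- c(seq(0, 1000, 100), seq(900, 0, -100))
  w <- fit_window(tri)
  expect_equal(unname(w[1]), min(which(tri >= 800)))
  expect_equal(unname(w[2]), max(which(tri >= 10)))
  expect_error(fit_window(rep(0, 10)), "flat")
  expect_error(fit_config(rise_fraction = 0.01, fall_fraction = 0.8))
})

test_that("noiseless self-generated curves are recovered almost exactly", {
  lib <- test_library()
  irf <- test_irf()
  node <- lib$mus_grid[6]
  model <- forward_curve(0.15, node)
  fit <- fit_optical_properties(model$values * 1e6, irf, lib)
  expect_lt(abs(fit$mua - 0.15) / 0.15, 0.005)
  expect_lt(abs(fit$mus_prime - node) / node, 0.005)
  expect_true(fit$converged)
  expect_false(fit$boundary)
})

test_that("recovery is amplitude invariant (shape-only fitting)", {
  lib <- test_library()
  irf <- test_irf()
  rec <- add_counting_noise(forward_curve(0.2, 10), 1e6, seed = 21,
                            wavelength_nm = 800)
  f1 <- fit_optical_properties(rec, irf, lib)
  rec2 <- rec
  rec2$counts <- rec$counts * 3L
  f2 <- fit_optical_properties(rec2, irf, lib)
  expect_equal(f2$mua, f1$mua, tolerance = 1e-6)
  expect_equal(f2$mus_prime, f1$mus_prime, tolerance = 1e-6)
  expect_equal(f2$amplitude / f1$amplitude, 3, tolerance = 1e-6)
})

test_that("noisy curves at 1e6 counts are recovered within a few percent", {
  lib <- test_library()
  irf <- test_irf()
  model <- forward_curve(0.2, 10)
  errs <- vapply(1:10, function(s) {
    f <- fit_optical_properties(
      add_counting_noise(model, 1e6, seed = 3000 + s, wavelength_nm = 800),
      irf, lib)
    c(abs(f$mua - 0.2) / 0.2, abs(f$mus_prime - 10) / 10)
  }, numeric(2))
  expect_lt(stats::median(errs[1, ]), 0.05)
  expect_lt(stats::median(errs[2, ]), 0.05)
})

test_that("estimator error decreases with total counts", {
  lib <- test_library()
  irf <- test_irf()
  model <- forward_curve(0.2, 10)
  rmse <- vapply(c(1e4, 1e6), function(n) {
    e <- vapply(1:8, function(s) {
      f <- fit_optical_properties(
        add_counting_noise(model, n, seed = 500 + s, wavelength_nm = 800),
        irf, lib)
      (f$mua - 0.2)^2 / 0.04
    }, numeric(1))
    sqrt(mean(e))
  }, numeric(1))
  expect_gt(rmse[1], rmse[2])
})

test_that("tidy and glance summarize a fit", {
  lib <- test_library()
  irf <- test_irf()
  f <- fit_optical_properties(forward_curve(0.1, 8)$values * 1e5, irf, lib)
  td <- tidy(f)
  expect_equal(td$term, c("mua", "mus_prime", "amplitude"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(f)
  expect_true(gl$converged)
})

test_that("fit_spectrum assembles sorted per-wavelength results", {
  lib <- test_library()
  irf <- test_irf()
  wls <- c(800, 650, 900)
  truth <- list(c(0.2, 10), c(0.3, 12), c(0.15, 8))
  recs <- purrr::map2(wls, truth, function(wl, tr)
    add_counting_noise(forward_curve(tr[1], tr[2]), 1e6,
                       seed = wl, wavelength_nm = wl))
  sp <- fit_spectrum(recs, irf, lib)
  expect_s3_class(sp, "optical_spectrum")
  expect_equal(sp$wavelength_nm, sort(wls))
  # permuting the inputs leaves the sorted output unchanged
  sp2 <- fit_spectrum(recs[c(2, 3, 1)], irf, lib)
  expect_equal(sp2$mua_cm1, sp$mua_cm1)
  expect_error(fit_spectrum(list(), irf, lib), "no records")
})

test_that("a single-wavelength fit completes within the speed contract", {
  lib <- test_library()
  irf <- test_irf()
  rec <- add_counting_noise(forward_curve(0.2, 10), 1e6, seed = 77,
                            wavelength_nm = 800)
  elapsed <- system.time(fit_optical_properties(rec, irf, lib))["elapsed"]
  expect_lt(elapsed, 5)
})
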