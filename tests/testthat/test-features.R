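# Spectral features: power law, spline peaks, paired t-tests, time courses,
# signature detection.

grid10 <- seq(650, 1100, 10)

test_that("power-law fit recovers flat and noiseless spectra exactly", {
  flat <- tibble::tibble(wavelength_nm = grid10, musp_cm1 = 6.9)
  f <- fit_power_law(flat)
  expect_equal(f$a, 6.9, tolerance = 1e-12)
  expect_equal(f$b, 0, tolerance = 1e-12)
  # native myocardium-like parameters
  sp <- tibble::tibble(wavelength_nm = grid10,
                       musp_cm1 = 6.9 * (grid10 / 650)^-1.2)
  f2 <- fit_power_law(sp)
  expect_equal(f2$a, 6.9, tolerance = 1e-10)
  expect_equal(f2$b, 1.2, tolerance = 1e-10)
  suppressWarnings({  # lm warns about an essentially perfect fit
    expect_equal(tidy(f2)$estimate, c(6.9, 1.2), tolerance = 1e-9)
    expect_gt(glance(f2)$r.squared, 0.999)
  })
})

test_that("power-law exponent is unbiased under multiplicative noise", {
  base <- 6.9 * (grid10 / 650)^-1.2
  bs <- vapply(1:200, function(s) {
    noisy <- base * exp(rfaoptics:::local_seed_int(
      s, stats::rnorm(length(base), 0, 0.05)))
    fit_power_law(tibble::tibble(wavelength_nm = grid10,
                                 musp_cm1 = noisy))$b
  }, numeric(1))
  expect_lt(abs(mean(bs) - 1.2), 0.02)
  expect_lt(stats::sd(bs), 0.1)
})

test_that("non-positive scattering values are excluded with a warning", {
  sp <- tibble::tibble(wavelength_nm = grid10,
                       musp_cm1 = 6.9 * (grid10 / 650)^-1.2)
  sp$musp_cm1[3] <- -1
  expect_warning(f <- fit_power_law(sp), "excluded")
  expect_equal(f$n, length(grid10) - 1)
})

test_that("spline peak localization resolves sub-grid peak positions", {
  mk <- function(centre, sigma = 20, sign = 1)
    tibble::tibble(wavelength_nm = grid10,
                   mua_cm1 = 0.2 + sign * 0.3 *
                     exp(-((grid10 - centre) / sigma)^2))
  # on-grid centre
  p1 <- locate_peak(mk(760), c(720, 800))
  expect_equal(p1$peak_lambda_nm, 760, tolerance = 0.1)
  # off-grid centre, within 1 nm
  p2 <- locate_peak(mk(764), c(720, 800))
  expect_lt(abs(p2$peak_lambda_nm - 764), 1)
  # minimum mode on an inverted band
  p3 <- locate_peak(mk(910, sign = -1), c(880, 940), mode = "minimum")
  expect_lt(abs(p3$peak_lambda_nm - 910), 1)
  # edge extrema are flagged
  expect_warning(locate_peak(mk(700), c(720, 800)), "edge")
  expect_error(locate_peak(mk(760), c(750, 770)), "at least 4")
})

test_that("injected shifts of a few nm are recovered within 1 nm from 10 nm
          sampling", {
  mk <- function(centre, band_centre = 760)
    tibble::tibble(wavelength_nm = grid10,
                   mua_cm1 = 0.2 + 0.3 * exp(-((grid10 - centre) / 20)^2))
  for (shift in c(4, 15)) {
    s <- peak_shift(mk(760), mk(760 + shift), c(720, 810))
    expect_lt(abs(s$shift_nm - shift), 1)
  }
  for (shift in c(-4, -5)) {
    s <- peak_shift(mk(975), mk(975 + shift), c(940, 1010))
    expect_lt(abs(s$shift_nm - shift), 1)
  }
  # identical spectra: zero shift
  s0 <- peak_shift(mk(760), mk(760), c(720, 800))
  expect_equal(s0$shift_nm, 0)
})

test_that("band narrowing is visible in the spline FWHM", {
  mk <- function(sigma)
    tibble::tibble(wavelength_nm = grid10,
                   mua_cm1 = 0.05 + 0.4 * exp(-((grid10 - 975) / sigma)^2))
  wide <- locate_peak(mk(30), c(930, 1020))
  narrow <- locate_peak(mk(24), c(930, 1020))
  expect_lt(narrow$fwhm_nm, wide$fwhm_nm)
  # half-prominence width tracks the generating width ratio approximately
  # (the sloping band-edge baseline biases it by a few percent)
  expect_equal(narrow$fwhm_nm / wide$fwhm_nm, 0.8, tolerance = 0.08)
})

test_that("paired t-test matches the closed form and flags degeneracy", {
  wl <- c(700, 800)
  native <- matrix(c(0, 0, 0, 0, 0, 0), nrow = 2)
  treated <- matrix(c(1, 5, 2, 5, 3, 5), nrow = 2)  # diffs row1: 1,2,3
  res <- per_wavelength_ttest(native, treated)
  expect_equal(res$statistic[1], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$p_value[1], 2 * stats::pt(-sqrt(12), 2), tolerance = 1e-12)
  expect_equal(round(res$p_value[1], 4), 0.0742)
  expect_false(res$significant[1])
  # zero-variance nonzero difference: p = 0, degenerate
  expect_true(res$degenerate[2])
  expect_equal(res$p_value[2], 0)
  # identical replicates: nothing significant
  same <- per_wavelength_ttest(treated, treated)
  expect_false(any(same$significant))
  expect_equal(same$p_value[2], 1)  # zero diff, zero variance
  # cross-check one wavelength against stats::t.test
  ref <- stats::t.test(treated[1, ], native[1, ], paired = TRUE)
  expect_equal(res$p_value[1], ref$p.value, tolerance = 1e-12)
})

test_that("t-test type-I error is calibrated at n = 3 pairs", {
  n_exp <- 2000
  hits <- rfaoptics:::local_seed_int(99, {
    vapply(seq_len(n_exp), function(i) {
      a <- matrix(stats::rnorm(3), nrow = 1)
      b <- matrix(stats::rnorm(3), nrow = 1)
      per_wavelength_ttest(a, b)$significant
    }, logical(1))
  })
  rate <- mean(hits)
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / n_exp))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_exp))
})

test_that("time courses normalize to their initial values", {
  df <- tibble::tibble(
    timestamp_s = rep(c(0, 10, 20), 2),
    wavelength_nm = rep(c(770, 910), each = 3),
    mua_cm1 = c(2, 4, 6, 5, 5, 5),
    musp_cm1 = c(1, 2, 3, 4, 4, 4))
  tc <- normalize_timecourse(df)
  expect_equal(tc$mua_cm1[tc$wavelength_nm == 770], c(1, 2, 3))
  expect_equal(tc$mua_cm1[tc$wavelength_nm == 910], c(1, 1, 1))
  expect_equal(tc$musp_cm1[tc$wavelength_nm == 770], c(1, 2, 3))
  # zero initial value flags the channel invalid
  df0 <- df
  df0$mua_cm1[1] <- 0
  tc0 <- normalize_timecourse(df0)
  expect_true(all(is.na(tc0$mua_cm1[tc0$wavelength_nm == 770])))
  expect_false(any(tc0$valid[tc0$wavelength_nm == 770]))
})

test_that("detect_signatures is null on identical spectra and
          order-consistent", {
  st <- evolve_state(trajectory_params(), treatment_protocol(105), 780)
  sp <- compose_absorption(st, default_basis(grid10))
  sp$musp_cm1 <- compose_scattering(st, grid10)$musp_cm1
  same <- detect_signatures(sp, sp)
  expect_false(any(same$detected[1:6]))
  expect_true(all(abs(same$magnitude[c(1, 2, 4, 5, 6)]) < 1e-9))
  # swapping native/treated negates the signed magnitudes
  s0 <- evolve_state(trajectory_params(), treatment_protocol(105), 0)
  nat <- compose_absorption(s0, default_basis(grid10))
  nat$musp_cm1 <- compose_scattering(s0, grid10)$musp_cm1
  fwd <- detect_signatures(nat, sp)
  bwd <- detect_signatures(sp, nat)
  for (k in c(1, 2, 4, 5, 6))
    expect_equal(bwd$magnitude[k], -fwd$magnitude[k], tolerance = 0.2)
})
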