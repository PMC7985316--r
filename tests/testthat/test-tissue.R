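# Synthetic tissue: chromophore basis, state composition, protocols,
# trajectories, dataset synthesis.

test_that("the default basis satisfies the band-structure invariants", {
  fine <- seq(650, 1100, 1)
  b <- default_basis(fine)
  tb <- as_tibble(b)
  expect_true(all(tb$hb >= 0 & tb$hbo2 >= 0 & tb$methb >= 0 & tb$water >= 0))
  # Hb peaks near 760 nm
  expect_gte(tb$wavelength_nm[which.max(tb$hb)], 750)
  expect_lte(tb$wavelength_nm[which.max(tb$hb)], 770)
  # water peaks near 975 nm
  expect_gte(tb$wavelength_nm[which.max(tb$water)], 965)
  expect_lte(tb$wavelength_nm[which.max(tb$water)], 985)
  # metHb dominates Hb across 780-900 nm
  sel <- tb$wavelength_nm >= 780 & tb$wavelength_nm <= 900
  expect_true(all(tb$methb[sel] > tb$hb[sel]))
  expect_error(default_basis(seq(600, 1100, 10)))
})

test_that("compose_absorption is linear and zero for an empty state", {
  b <- default_basis()
  empty <- tissue_state(c_hb = 0, c_hbo2 = 0, c_methb = 0,
                        water_fraction = 0)
  expect_true(all(compose_absorption(empty, b)$mua_cm1 == 0))
  st <- tissue_state()
  st2 <- tissue_state(c_hb = 2 * st$c_hb, c_hbo2 = 2 * st$c_hbo2,
                      c_methb = 2 * st$c_methb,
                      water_fraction = min(2 * st$water_fraction, 1))
  # doubling every concentration doubles mua (water clamped at 1 avoided)
  st$water_fraction <- 0.4
  st2$water_fraction <- 0.8
  expect_equal(compose_absorption(st2, b)$mua_cm1,
               2 * compose_absorption(st, b)$mua_cm1, tolerance = 1e-12)
})

test_that("water band shift and narrowing propagate to the composed
          spectrum", {
  b <- default_basis()
  pure <- function(shift, width)
    tissue_state(c_hb = 0, c_hbo2 = 0, c_methb = 0, water_fraction = 1,
                 water_shift_nm = shift, water_width_factor = width)
  ref <- compose_absorption(pure(0, 1), b)
  mod <- compose_absorption(pure(-5, 0.8), b)
  s <- peak_shift(ref, mod, c(930, 1020))
  # oracle: dense evaluation of the composed spectra themselves
  dense <- seq(930, 1020, 0.01)
  dense_peak <- function(st)
    dense[which.max(compose_absorption(st, b, grid = dense)$mua_cm1)]
  dense_shift <- dense_peak(pure(-5, 0.8)) - dense_peak(pure(0, 1))
  expect_equal(s$shift_nm, dense_shift, tolerance = 0.2 / abs(dense_shift))
  # the injected -5 nm dominates the composite-band pull
  expect_lt(abs(s$shift_nm - (-5)), 0.6)
  expect_equal(s$treated_fwhm_nm / s$native_fwhm_nm, 0.8, tolerance = 0.07)
})

test_that("temperature profile ramps linearly, holds, and cools", {
  pr <- treatment_protocol(105, ramp_s = 180, hold_s = 600,
                           cooling_s = 600, cooling_tau_s = 200)
  expect_equal(temperature_profile(pr, 0), 23)
  expect_equal(temperature_profile(pr, 90), (23 + 105) / 2)
  expect_equal(temperature_profile(pr, 180), 105)
  expect_equal(temperature_profile(pr, 500), 105)
  tt <- seq(0, 780, 5)
  expect_true(all(diff(temperature_profile(pr, tt)) >= 0))
  expect_lt(temperature_profile(pr, 781), 105)
  expect_gt(temperature_profile(pr, 5000), 23 - 1e-9)
})

test_that("trajectories respect the temperature thresholds", {
  p <- trajectory_params()
  pr70 <- treatment_protocol(70)
  s0 <- evolve_state(p, pr70, 0)
  expect_equal(s0$c_methb, 0)
  expect_equal(s0$charring_amp, 0)
  expect_equal(s0$water_shift_nm, 0)
  expect_equal(s0$water_width_factor, 1)
  # a 70 C protocol never crosses the metHb (75 C) or charring (100 C)
  # thresholds
  for (t in c(100, 400, 780)) {
    st <- evolve_state(p, pr70, t)
    expect_equal(st$c_methb, 0)
    expect_equal(st$charring_amp, 0)
  }
  # a 105 C protocol crosses both
  pr105 <- treatment_protocol(105)
  end <- evolve_state(p, pr105, 780)
  expect_gt(end$c_methb, 0)
  expect_gt(end$charring_amp, 0)
  expect_gte(end$a / s0$a, 1)
  # scattering plateau: max over the course lands near the configured x3
  ratio <- max(vapply(seq(0, 780, 20), function(t)
    evolve_state(p, pr105, t)$a, numeric(1))) / s0$a
  expect_gte(ratio, 2.5)
  expect_lte(ratio, 3.5)
  # and near x2 for the 70 C protocol
  ratio70 <- max(vapply(seq(0, 780, 20), function(t)
    evolve_state(p, pr70, t)$a, numeric(1))) / s0$a
  expect_gte(ratio70, 1.7)
  expect_lte(ratio70, 2.3)
})

test_that("trajectories are continuous and keep states valid", {
  p <- trajectory_params()
  pr <- treatment_protocol(105, cooling_s = 400)
  tt <- seq(0, 1100, 5)
  as <- vapply(tt, function(t) evolve_state(p, pr, t)$a, numeric(1))
  ws <- vapply(tt, function(t) evolve_state(p, pr, t)$water_fraction,
               numeric(1))
  # continuous: no discontinuous jumps between 5 s samples (the logistic
  # denaturation rise itself is the steepest feature)
  expect_lt(max(abs(diff(as)) / as[-1]), 0.2)
  expect_true(all(ws >= 0 & ws <= 1))
  expect_true(all(as > 0))
})

test_that("dataset synthesis matches the protocol bookkeeping and is
          reproducible", {
  lib <- test_library()
  irf <- test_irf()
  p <- trajectory_params()
  # broadband: 13 timestamps x 46 wavelengths
  ds <- generate_dataset(p, treatment_protocol(105), library = lib,
                         irf = irf, counts_per_curve = 1e4, seed = 50,
                         timestamps_s = c(0, 780))
  expect_equal(length(ds$records), 2 * 46)
  expect_equal(nrow(ds$truth), 2 * 46)
  full_ts <- generate_dataset(p, treatment_protocol(105), library = lib,
                              irf = irf, counts_per_curve = 1e4, seed = 50,
                              timestamps_s = seq(0, 720, 60))
  expect_equal(length(full_ts$records), 13 * 46)
  # five-wavelength mode: 61 timestamps x 5 wavelengths
  ds5 <- generate_dataset(p, treatment_protocol(
    105, sampling = "five_wavelength"), library = lib, irf = irf,
    counts_per_curve = 1e4, seed = 51, timestamps_s = seq(0, 600, 100))
  expect_equal(sort(unique(ds5$truth$wavelength_nm)),
               c(770, 840, 910, 980, 1060))
  # determinism
  ds2 <- generate_dataset(p, treatment_protocol(105), library = lib,
                          irf = irf, counts_per_curve = 1e4, seed = 50,
                          timestamps_s = c(0, 780))
  expect_identical(ds$records[[30]]$counts, ds2$records[[30]]$counts)
  expect_identical(ds$truth, ds2$truth)
})

test_that("replicate samples stay within the configured variability", {
  lib <- test_library()
  irf <- test_irf()
  ds <- generate_dataset(trajectory_params(), treatment_protocol(105),
                         library = lib, irf = irf, counts_per_curve = 1e4,
                         seed = 60, timestamps_s = 0, n_replicates = 3,
                         replicate_sd = 0.03)
  tr <- tidyr::pivot_wider(ds$truth, id_cols = "wavelength_nm",
                           names_from = "replicate",
                           values_from = "mua_cm1")
  rel <- apply(as.matrix(tr[-1]), 1, function(x) stats::sd(x) / mean(x))
  expect_lt(max(rel), 0.05)
})
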