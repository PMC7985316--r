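# Photon transport: Monte Carlo slab transmittance, Beer-Lambert scaling,
# RTE rescaling, diffusion-approximation oracle.

test_that("geometry and grid constructors enforce their invariants", {
  expect_error(slab_geometry(thickness_cm = -1))
  expect_error(slab_geometry(n_sample = 0.9))
  expect_error(time_grid(n_bins = 0))
  g <- time_grid(16, 2.5)
  expect_equal(length(bin_centers(g)), 16)
  expect_equal(diff(bin_edges(g)), rep(2.5, 16))
  expect_equal(ballistic_time_ps(slab_geometry()), 1 * 1.41 / 0.0299792458)
})

test_that("MC transmittance is causal and deterministic given the seed", {
  tp <- test_reference_tpsf()
  tb <- ballistic_time_ps(slab_geometry())
  early <- bin_edges(tp$grid)[-1] <= tb
  expect_true(sum(tp$values[early]) == 0)
  expect_gt(tp$bookkeeping$n_detected, 0)
  # determinism: same seed, same curve
  tp2 <- simulate_reference_tpsf(slab_geometry(), 10, test_grid(),
                                 n_photons = 1e5, seed = 17)
  expect_identical(tp$values, tp2$values)
  # a different seed gives a different realization
  tp3 <- simulate_reference_tpsf(slab_geometry(), 10, test_grid(),
                                 n_photons = 1e5, seed = 18)
  expect_false(identical(tp$values, tp3$values))
})

test_that("more scattering lengthens the mean transit time", {
  t5 <- simulate_reference_tpsf(slab_geometry(), 5, test_grid(),
                                n_photons = 1e5, seed = 2)
  t10 <- test_reference_tpsf()
  expect_gt(mean_transit_time(t10), mean_transit_time(t5))
})

test_that("weight bookkeeping conserves energy to 1e-6 relative", {
  for (mua in c(0, 0.3)) {
    tp <- simulate_reference_tpsf(slab_geometry(), 8, test_grid(),
                                  n_photons = 5e4, seed = 5, mua = mua)
    bk <- tp$bookkeeping
    total <- bk$transmitted_weight + bk$reflected_weight +
      bk$absorbed_weight + bk$late_weight + bk$roulette_net_weight
    expect_lt(abs(total - 1), 1e-6)
  }
  # with roulette enabled the balance still closes
  tp <- simulate_reference_tpsf(slab_geometry(), 8, test_grid(),
                                n_photons = 2e4, seed = 6, mua = 1.5,
                                roulette_threshold = 1e-2)
  bk <- tp$bookkeeping
  total <- bk$transmitted_weight + bk$reflected_weight + bk$absorbed_weight +
    bk$late_weight + bk$roulette_net_weight
  expect_lt(abs(total - 1), 1e-6)
})

test_that("apply_absorption implements exp(-mua*v*t) per bin", {
  tp <- test_reference_tpsf()
  # identity at zero absorption
  expect_identical(apply_absorption(tp, 0)$values, tp$values)
  # the printed factor: n = 1.41, mua = 0.1 /cm, t = 1000 ps
  v <- 0.0299792458 / 1.41
  expect_equal(exp(-0.1 * v * 1000), 0.1193, tolerance = 1e-3)
  out <- apply_absorption(tp, 0.1)
  k <- which(tp$values > 0)
  expect_equal(out$values[k],
               tp$values[k] * exp(-0.1 * v * bin_centers(tp$grid)[k]),
               tolerance = 1e-12)
  # composition additivity, bin-wise to machine precision
  ab <- apply_absorption(apply_absorption(tp, 0.07), 0.13)
  once <- apply_absorption(tp, 0.2)
  expect_equal(ab$values, once$values, tolerance = 1e-12)
  expect_error(apply_absorption(tp, -0.1))
})

test_that("direct MC with absorption matches Beer-Lambert reweighting of the
          same-seed null-absorption run", {
  g <- slab_geometry()
  null_run <- simulate_reference_tpsf(g, 10, test_grid(),
                                      n_photons = 5e4, seed = 9)
  mua_run <- simulate_reference_tpsf(g, 10, test_grid(),
                                     n_photons = 5e4, seed = 9, mua = 0.2)
  replay <- apply_absorption(null_run, 0.2)
  # same trajectories; only the bin-centre vs exact-time evaluation differs
  k <- null_run$values > 0
  expect_equal(mua_run$values[k], replay$values[k], tolerance = 0.01)
})

test_that("scale_tpsf applies the RTE similarity transform", {
  tp <- test_reference_tpsf()
  # k = 1 is the identity
  s1 <- scale_tpsf(tp, 1)
  expect_equal(s1$values, tp$values)
  expect_equal(s1$grid$bin_width_ps, tp$grid$bin_width_ps)
  # transmitted fraction is conserved for any k
  s2 <- scale_tpsf(tp, 2)
  expect_equal(sum(s2$values), sum(tp$values))
  expect_equal(s2$mus_prime, 5)
  expect_equal(s2$geometry$thickness_cm, 2)
  expect_equal(s2$grid$bin_width_ps, 40)
  expect_error(scale_tpsf(apply_absorption(tp, 0.1), 2))
})

test_that("rescaled MC agrees with a fresh MC at the scaled geometry", {
  # MC(L=1, mus'=10) rescaled by k=2 vs MC(L=2, mus'=5, detector x2)
  a <- simulate_reference_tpsf(slab_geometry(1), 10, test_grid(),
                               n_photons = 2e5, seed = 11)
  sc <- scale_tpsf(a, 2)
  b <- simulate_reference_tpsf(slab_geometry(2, detector_radius_cm = 1),
                               5, time_grid(512, 40), n_photons = 2e5,
                               seed = 99)
  ca <- sc$values * 2e5
  cb <- b$values * 2e5
  keep <- (ca + cb) >= 10
  N1 <- sum(ca[keep]); N2 <- sum(cb[keep])
  chi <- sum((ca[keep] / N1 - cb[keep] / N2)^2 /
               ((ca[keep] + cb[keep]) / (N1 * N2)))
  p <- stats::pchisq(chi, sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("diffusion approximation factorizes absorption and has causal-limit
          behaviour", {
  g <- slab_geometry()
  tg <- test_grid()
  da0 <- da_transmittance(g, 0, 10, tg)
  # flux vanishes at both ends of the time axis
  expect_equal(da0$values[1], 0)
  expect_lt(da0$values[tg$n_bins] / max(da0$values), 1e-6)
  # da(mua) == apply_absorption(da(0), mua) bin-wise to machine precision
  da_a <- da_transmittance(g, 0.05, 10, tg)
  expect_equal(da_a$values, apply_absorption(da0, 0.05)$values,
               tolerance = 1e-14)
  expect_warning(da_transmittance(g, 1, 5, tg), "diffusive")
})

test_that("DA and MC agree on the normalized shape in the diffusive regime", {
  # moderate-n version of the oracle comparison (full-n in acceptance)
  g <- slab_geometry()
  mc <- fixture("mc_da", function()
    simulate_reference_tpsf(g, 10, time_grid(256, 40), n_photons = 1e6,
                            seed = 42))
  mc <- apply_absorption(mc, 0.05)
  da <- da_transmittance(g, 0.05, 10, time_grid(256, 40))
  w <- fit_window(mc$values)
  i <- w[1]:w[2]
  mcn <- mc$values[i] / sum(mc$values[i])
  dan <- da$values[i] / sum(da$values[i])
  # moderate photon count: counting noise in the 1% tail dominates the bound
  expect_lt(max(abs(dan - mcn) / mcn), 0.15)
})

test_that("an empty curve is flagged, not silently zero", {
  # thick, highly scattering slab with a tiny detector and few photons
  g <- slab_geometry(5, detector_radius_cm = 0.01)
  expect_warning(
    tp <- simulate_reference_tpsf(g, 50, time_grid(64, 10),
                                  n_photons = 1e4, seed = 1),
    "empty")
  expect_true(tp$bookkeeping$empty)
})
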