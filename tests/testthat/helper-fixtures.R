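# Shared fixtures, built once per test run and cached for the session.
# All Monte Carlo fixtures are generated in code from fixed seeds.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

test_grid <- function() time_grid(512, 20)

# Standard inversion library: default slab, 10 geometric nodes over the
# reduced-scattering range the synthetic trajectories visit.
test_library <- function() fixture("lib", function() {
  build_library(slab_geometry(), default_mus_grid(3, 25, 10), test_grid(),
                n_photons = 6e5, seed = 3)
})

test_irf <- function() fixture("irf", function() {
  synthesize_irf(80, test_grid(), peak_position_ps = 400)
})

# Forward model for a single wavelength: expected counts shape
forward_curve <- function(mua, musp, lib = test_library(), irf = test_irf()) {
  convolve_irf(apply_absorption(interpolate_library(lib, musp), mua), irf)
}

# A discrete delta "IRF" (all weight in one bin) for identity checks
new_irf_for_test <- function(grid, which_bin = 1) {
  v <- numeric(grid$n_bins)
  v[which_bin] <- 1
  rfaoptics:::new_irf(grid, v, fwhm_ps = grid$bin_width_ps,
                      peak_position_ps = bin_centers(grid)[which_bin])
}

# A reference MC curve reused by transport tests (1e5 photons)
test_reference_tpsf <- function() fixture("ref_tpsf", function() {
  simulate_reference_tpsf(slab_geometry(), 10, test_grid(),
                          n_photons = 1e5, seed = 17)
})
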