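# rfaoptics

Time-domain diffuse optical monitoring of radiofrequency ablation (RFA).

During RFA, tissue is heated through coagulation (around 70 °C) and, in
over-treatment, past 100 °C into charring. Broadband time-domain diffuse
optical spectroscopy (TD-DOS) can follow this process non-invasively: short
laser pulses are sent through the tissue slab, the distribution of
time-of-flight (DTOF) of transmitted photons is recorded per wavelength, and
the temporal shape of each curve disentangles the absorption coefficient
μa(λ) from the reduced scattering coefficient μs′(λ). The recovered spectra
carry distinct thermal signatures — dehydration, protein denaturation,
methemoglobin formation, peak shifts of deoxyhemoglobin and water, and
charring — that can grade treatment progress in real time.

`rfaoptics` implements the full computation chain for this kind of
monitoring, for researchers in biomedical optics who need a tested,
reproducible reference pipeline:

* **Forward model** — "white" Monte Carlo photon transport through a slab
  (isotropic scattering with μs = μs′, Fresnel boundaries, exact exit-time
  scoring) at null absorption; absorption added analytically with the
  Beer–Lambert factor `exp(-μa·v·t)`; the scaling property of the radiative
  transfer equation (lengths ×k, μs′ ×1/k, time ×k) to reuse simulations; a
  closed-form diffusion-approximation slab solution (extrapolated-boundary
  image sources) as the analytic oracle.
* **Instrument model** — instrument response function (IRF) synthesis,
  discrete convolution of model curves with the IRF, Poisson photon-counting
  noise.
* **Inversion** — per-wavelength fits of IRF-convolved, library-interpolated
  model curves to measured DTOFs over the region between 80% of the peak on
  the rising edge and 1% on the falling edge, with a free amplitude (the fit
  uses only the temporal shape), recovering μa and μs′ per wavelength and
  assembling broadband spectra (650–1100 nm, 10 nm steps).
* **Spectral features** — Mie power-law fit `μs′(λ) = a (λ/λ₀)^-b`
  (λ₀ = 650 nm), cubic-spline peak localization resolving few-nm shifts from
  10 nm sampling, per-wavelength paired t-tests (α = 0.05), normalized
  kinetic time courses, and a detector for the seven treatment signatures.
* **Synthetic tissue** — a parametric chromophore basis (Hb, HbO₂, metHb,
  water, charring) and deterministic state trajectories under 70 °C /
  105 °C heating protocols, so the whole pipeline is testable end to end
  without any external data.

## Worked example

Recover optical properties from a synthetic noisy measurement:

```r
library(rfaoptics)

geom <- slab_geometry(thickness_cm = 1)   # n = 1.41 tissue, n = 1.5 plates
grid <- time_grid(512, 20)                # 20 ps bins over 10.24 ns
lib  <- build_library(geom, default_mus_grid(3, 25, 10), grid,
                      n_photons = 2e5, seed = 7)
irf  <- synthesize_irf(fwhm_ps = 80, grid, peak_position_ps = 400)

# synthesize a DTOF at mua = 0.2 /cm, mus' = 10 /cm with 1e6 counts
curve <- convolve_irf(apply_absorption(interpolate_library(lib, 10), 0.2), irf)
dtof  <- add_counting_noise(curve, total_counts = 1e6, seed = 11,
                            wavelength_nm = 800)

fit <- fit_optical_properties(dtof, irf, lib)
fit
#> <od_fit> mua = 0.2002 /cm, mus' = 9.998 /cm (amplitude 4.39e+07)
tidy(fit)
#> # A tibble: 3 × 3
#>   term          estimate std.error
#>   <chr>            <dbl>     <dbl>
#> 1 mua              0.200   0.00207
#> 2 mus_prime       10.00    0.0308
#> 3 amplitude 43862222.     NA
```

The recovered absorption (0.200 /cm) and reduced scattering (10.00 /cm)
match the generating values to a fraction of a percent; the quoted standard
errors come from the curvature of the Poisson deviance. A full treatment
simulation goes through `treatment_protocol()`, `trajectory_params()` and
`generate_dataset()`, is fitted with `fit_spectrum()`, and summarized with
`fit_power_law()`, `peak_shift()` and `detect_signatures()`; see the
vignette in `vignettes/` for the models and defaults.

A thin command-line front end (`inst/cli/rfaoptics.R`) exposes
`build-library`, `simulate`, `fit`, `features` and `timecourse` subcommands
over the same functions, reading and writing the package's delimited-text
DTOF/IRF/spectrum formats.

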