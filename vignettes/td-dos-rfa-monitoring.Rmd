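---
title: "Monitoring thermal ablation with time-domain diffuse optics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring thermal ablation with time-domain diffuse optics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rfaoptics)
```

This vignette is the package's own account of the science it implements: the
forward and inverse models, the quantities they assume, the defaults and why
they were chosen, and what the synthetic-tissue generator does and does not
emulate.

## The measurement and its model

A picosecond laser pulse enters one face of a tissue slab; photons scatter
diffusely and a detector on the opposite face histograms their arrival times
(a DTOF: distribution of time-of-flight). Scattering controls how long
photons wander — more scattering stretches and delays the curve — while
absorption multiplies the whole curve by the Beer–Lambert factor
$e^{-\mu_a v t}$, where $v = c/n$ is the speed of light in the medium and
$t$ the elapsed time. Because the two coefficients deform the temporal shape
in distinct ways, a single time-resolved curve determines both
$\mu_a$ and $\mu_s'$, with no intensity calibration: amplitude is a free
parameter throughout.

### White Monte Carlo forward model

`simulate_reference_tpsf()` propagates photons through the slab at **zero
absorption** ("white" Monte Carlo). Scattering is isotropic with
$\mu_s = \mu_s'$: only the reduced coefficient is identifiable in diffuse
transmittance (similarity relation), so simulating an anisotropic phase
function would add a parameter the data cannot constrain. Unpolarized
Fresnel reflection/refraction is applied at both faces using the sample
(default $n = 1.41$, soft tissue) and external (default $n = 1.5$, the PVC
holder plates) indices; internally reflected photons continue propagating.
Photons leaving the exit face inside the detector radius score their exact
exit time. Absorption is then added analytically by `apply_absorption()` —
exact because every photon's path length is $v t$ — and one simulation
serves all absorption values. The scaling property of the radiative transfer
equation (`scale_tpsf()`: lengths $\times k$, $\mu_s' \times 1/k$, time
$\times k$) extends one geometry to a family.

Bookkeeping records transmitted, reflected, absorbed and time-truncated
weight so that energy conservation is assertable to $10^{-6}$. Survival
roulette is implemented (threshold configurable) but off by default: the
time-grid cap bounds path lengths, weights never approach the usual
$10^{-4}$ threshold for the absorption range of interest, and keeping it off
makes a same-seed run with absorption follow bit-identical trajectories to
its null-absorption twin — the Beer–Lambert factorization is then testable
bin by bin.

Defaults: detector radius 0.5 cm (the real instrument used a 1 mm fiber, but
at 1 cm slab thickness the transmitted *shape* depends only weakly on the
collection radius, and a larger detector collects photons at a usable rate;
numerical aperture is not modelled); time grid 4096 × 2.5 ps (resolves a
sub-90 ps IRF; spans 10.24 ns, inside one 80 MHz laser period so
wrap-around never enters); RNG is a counter-seeded xoshiro256++ independent
of R's RNG, so every stochastic operation takes an explicit integer seed and
reproduces exactly.

### Diffusion-approximation oracle

`da_transmittance()` implements the standard time-resolved slab solution of
the diffusion approximation with extrapolated boundary conditions: an
infinite series of image sources (truncated at 8 pairs, fully converged for
slabs a few transport lengths thick), a source depth $z_0 = 1/\mu_s'$,
$D = 1/(3\mu_s')$, and an extrapolation length $z_e = 2AD$ with $A$ computed
by numerically integrating the unpolarized Fresnel reflectance — valid for
any index ratio, including the tissue-into-denser-plate case here. The
lateral Gaussian spread is integrated over the detector disk. This analytic
curve is the package's independent oracle for the Monte Carlo model in the
diffusive regime; it is *not* used for fitting, because at the high
absorption and modest scattering of native tissue the diffusion
approximation distorts recovered properties — which is the reason the
Monte Carlo library exists.

### Library and interpolation

`build_library()` simulates one null-absorption curve per reduced-scattering
node (default 25 geometric nodes over 1–70 cm⁻¹, covering reported tissue
values ~5.6–55.8 cm⁻¹ with margin; node $i$ uses seed + $i$ − 1 so rebuilds
are bit-identical). Between nodes, `interpolate_library()` area-normalizes
the two bracketing curves, rescales each in time so its mean transit time
matches the log-linearly interpolated target, mixes the shapes linearly in
$\log \mu_s'$, and restores the log-interpolated transmitted fraction. Curve
shape varies smoothly in $\log \mu_s'$, which geometric node spacing and
log-space mixing exploit; the interpolant is exact at nodes, continuous, and
monotone in mean transit time. Queries outside the grid raise an error —
extrapolated Monte Carlo shapes would be silently wrong. Persistence is
delimited text plus a JSON manifest, round-tripping bit-exactly.

## Instrument model

The measured curve is the medium's response convolved with the instrument
response function (IRF), so the pipeline convolves **after** applying
absorption — the two operations do not commute and the order matters.
`synthesize_irf()` provides a gaussian (default, FWHM 80 ps, representative
of a sub-90 ps TCSPC chain) or an exponentially modified gaussian (silicon
photomultipliers have diffusion tails); real measured IRFs can be loaded
through `read_irf()`. Convolution is the direct discrete sum (cross-checked
against FFT convolution to $10^{-10}$), and `add_counting_noise()` draws
independent Poisson counts per bin with an optional uniform dark-count
background — the statistics of time-correlated single-photon counting,
verified by an index-of-dispersion test.

## Inversion

`fit_optical_properties()` minimizes, by default, the Poisson deviance
between the measured counts and
$A \cdot \mathrm{IRF} * \big(e^{-\mu_a v t}\, \mathrm{lib}(\mu_s')\big)$
inside the fit window: from the first bin at ≥80% of the peak on the rising
edge to the last bin at ≥1% on the falling edge. The window thresholds are
relative, making the whole fit amplitude invariant; the scale $A$ is
profiled out in closed form (the Poisson maximum-likelihood scale is the
count ratio). Weighted least squares is available for parity with common
practice, but counts are Poisson and the deviance is the matching
likelihood. A constant background is estimated from the first 5% of bins —
as the *median*, because the convolution's rising edge can leak into the
pre-peak region and a mean estimate biases the recovered absorption
upward — and subtracted before fitting.

The optimizer is derivative-free: a coarse scan over library nodes *and
segment midpoints* crossed with a log-spaced absorption grid, followed by
one-dimensional profiled-$\mu_a$ refinement at the scan winner's
neighbourhood, then Nelder–Mead in $(\log \mu_a, \log \mu_s')$ with up to
six restarts (convergence: relative objective change below $10^{-8}$). The
extra seeding stages exist because the deviance valley is narrow and curved,
and the piecewise library interpolation leaves shallow ridges at segment
boundaries that can trap a single simplex pass; both failure modes were
observed and are covered by round-trip tests. Parameter uncertainties come
from the curvature (finite-difference Hessian) of half the deviance.
Degenerate inputs fail loudly: flat or empty curves raise an error at the
window stage, non-convergence and library-boundary solutions are flagged on
the result, and failed wavelengths appear as missing rows in
`fit_spectrum()` output, never interpolated over.

## Spectral features

* **Power law**: `fit_power_law()` fits
  $\mu_s'(\lambda) = a(\lambda/\lambda_0)^{-b}$, $\lambda_0 = 650$ nm, by
  least squares in log–log space; $a$ tracks scatterer density, $b$
  effective scatterer size. Non-positive values are excluded with a warning.
* **Peaks and shifts**: `locate_peak()` interpolates the 10 nm-sampled
  spectrum with a natural cubic spline and finds extrema on a 0.1 nm
  evaluation grid, which resolves the few-nm band shifts of treatment from
  coarse sampling; band-edge extrema are flagged as not being true peaks.
  Width is the half-prominence full width above a baseline taken as the mean
  of the spline at the two band edges (the bands are chosen so their edges
  sit near local minima). Default bands: Hb 720–800 nm, emerging peak
  810–870 nm (covering both the 830 and 840 nm readings), 910 nm valley
  880–940 nm, water 940–1010 nm; all configurable.
* **Significance**: `per_wavelength_ttest()` applies a two-sided paired
  t-test per wavelength at α = 0.05 with *no* multiple-testing correction —
  matching the per-wavelength significance stars convention — with a
  Benjamini–Hochberg option off by default. Zero-variance differences
  report p = 0 (nonzero mean) or p = 1 (zero mean) with a degenerate flag.
* **Signatures**: `detect_signatures()` reports, for each of the seven
  treatment signatures, a boolean and a signed magnitude. Band-mean changes
  are log-ratios so that swapping the two spectra exactly negates the
  magnitude; the 840 nm emergence is quantified as spline prominence gained
  over the native spectrum; the seventh signature (scattering below the
  critically treated state) needs the 70 °C reference spectrum and is `NA`
  without it.

## Synthetic tissue generator

The generator defines the study conditions under which the pipeline is
validated. Its chromophore basis (`default_basis()`) is **parametric** —
sums of gaussian bands and exponential edges shaped to reproduce the
qualitative band structure of the real absorbers: deoxyhemoglobin peaking at
760 nm, oxyhemoglobin broad and featureless, methemoglobin exceeding both
heme species over 780–900 nm with its thermal band near 840 nm, water
peaking at 975 nm with a long-wavelength edge, and charring decaying
exponentially with wavelength (decay constant 200 nm). These are synthetic
stand-ins, not digitized literature spectra; `read_extinction_table()`
loads real tabulated data for users who have it.

State trajectories (`evolve_state()`) are deterministic closed forms driven
by the temperature profile (linear ramp over 180 s — slightly under three
minutes — constant hold for 600 s, optional exponential passive cooling to
23 °C):

* scattering amplitude $a$ rises logistically with temperature (onset
  58 °C, steepness 4.5 °C) to a plateau gain of ×2 at a 70 °C target and
  ×3 at 105 °C, drifts up slowly during a sub-charring hold, and declines
  exponentially while above the 100 °C charring onset — so the
  over-treatment run ends *below* the critical-treatment run;
* heme chromophores degrade slowly above 50 °C and convert to
  methemoglobin first-order above 75 °C; a 70 °C protocol therefore never
  forms metHb, and the 840 nm peak emerges only in over-treatment (the
  mechanistic reading of why that peak is stronger at 105 °C);
* water is lost at a rate proportional to temperature excess, producing the
  long-wavelength absorption decrease at both targets;
* the Hb band redshifts and the water band blueshifts and narrows following
  the maximum temperature reached, with piecewise-linear maps anchored at
  (70 °C, 105 °C) → (+4, +15) nm for Hb and (−4, −5) nm with width factors
  (0.85, 0.75) for water; shifts persist on cooling except the configured
  partially reversible fractions of the water shift and width;
* charring absorption grows linearly in time above 100 °C.

The kinetic *forms* (logistic, first-order, exponential) are the
implementer's choice — the phenomenology constrains plateaus, thresholds and
end states, not rate laws — and every rate and threshold lives in
`trajectory_params()` with the defaults above. The conversion fraction of
metHb and the water-loss fraction have no reported values; their defaults
(≈40% conversion and ≈60% water loss at the end of an over-treatment run)
were chosen once to give the signature magnitudes a realistic size.

`generate_dataset()` composes state → $(\mu_a, \mu_s')$ → library
interpolation → Beer–Lambert → IRF convolution → Poisson noise (default
$10^6$ counts per curve) for every timestamp and wavelength of the protocol
(broadband: 46 wavelengths 650–1100 nm every minute, 13 spectra per run;
kinetics: 770/840/910/980/1060 nm every 10 s for 600 s), optionally with
replicate "samples" perturbed by ~3% log-normal factors (inter-sample
deviation under 5%).

What the generator does **not** emulate: spatial heterogeneity of the
ablation zone and partial-volume effects, vessel heat sinks, microbubble
scattering transients, wavelength-dependent IRF drift, detector afterpulsing
and pile-up, and any real chromophore fine structure beyond the band
approximations. Passing tests therefore demonstrate that the *pipeline*
recovers what the forward model encodes under realistic counting noise —
not that the parametric tissue model reproduces any particular sample.

## Problem sizes and numerical choices

The test suite and acceptance script run everything at reduced but
representative sizes, chosen once as a sensible accuracy/runtime balance:
512 × 20 ps time grids, a 10-node library over 3–25 cm⁻¹ covering the
synthetic trajectories, $6\text{–}8 \times 10^5$ photons per library node,
$10^6$–$10^7$ photons for oracle comparisons, $10^6$ counts per synthetic
DTOF, 50-seed recovery studies and $10^4$-replicate significance
calibrations. The shape comparison between Monte Carlo and the diffusion
approximation uses 25 ps analysis bins so that tail counting noise does not
dominate the comparison. Fits converge in a few hundred milliseconds on one
CPU with a prebuilt library.

## Known limitations

* Transmittance geometry only; reflectance and layered media are out of
  scope.
* The similarity relation (isotropic scattering) is exact for the quantities
  inferred here but precludes studying anisotropy effects.
* The diffusion solution is an oracle, not a fitting engine; its accuracy
  degrades exactly where the Monte Carlo approach is needed.
* The spline shift estimator reads the shift of the *composite* band; when
  fixed spectral components overlap a shifted band, the measured shift is
  attenuated relative to the injected basis shift (visible in the
  generator's water band, where reported blueshifts are smaller in
  magnitude than the injected −4/−5 nm).
* No spectrally constrained (multi-wavelength simultaneous) fitting and no
  chromophore concentration unmixing: the feature set quantifies spectral
  signatures, it does not invert them for concentrations.
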