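# Synthetic heated-tissue generator: parametric chromophore basis, tissue
# state trajectories under an RF heating protocol, and full DTOF dataset
# synthesis so the whole pipeline is testable without external data.

#' Parametric chromophore basis
#'
#' Packaged parametric approximations (sums of gaussian bands plus
#' exponential edges) of the near-infrared specific absorption of the tissue
#' chromophores that drive the treatment signatures: deoxyhemoglobin (local
#' maximum near 760 nm), oxyhemoglobin, methemoglobin (dominating both heme
#' species over 780--900 nm), water (main band near 975 nm, shiftable and
#' width-scalable to emulate thermal hydrogen-bond weakening), and a
#' charring term decaying exponentially with wavelength. These are synthetic
#' stand-ins shaped to reproduce the qualitative band structure of tabulated
#' extinction data, not digitized literature values;
#' [read_extinction_table()] loads real tabulated spectra for users who have
#' them.
#'
#' @param grid Wavelength grid, nm, within 650--1100.
#' @return A `chromophore_basis`: evaluable functions `hb(lambda)`,
#'   `hbo2(lambda)`, `methb(lambda)`, `water(lambda, shift_nm, width_factor)`,
#'   `charring(lambda, amplitude, decay_nm)`, plus the grid. Units are 1/cm
#'   per unit concentration (per unit volume fraction for water).
#' @examples
#' b <- default_basis()
#' tibble::as_tibble(b)
#' @export
default_basis <- function(grid = seq(650, 1100, 10)) {
  stopifnot(min(grid) >= 650, max(grid) <= 1100)
  gauss <- function(l, mu, sig) exp(-((l - mu) / sig)^2)
  structure(list(
    grid = grid,
    hb = function(l)
      0.20 * exp(-(l - 650) / 70) + 0.55 * gauss(l, 760, 21) +
        0.25 * gauss(l, 905, 95),
    hbo2 = function(l)
      0.10 + 0.28 * gauss(l, 915, 85),
    methb = function(l)
      0.70 * exp(-(l - 650) / 150) + 0.55 * gauss(l, 840, 55),
    water = function(l, shift_nm = 0, width_factor = 1)
      0.42 * gauss(l, 975 + shift_nm, 30 * width_factor) +
        0.012 * gauss(l, 836, 25) + 0.30 * exp((l - 1100) / 45) + 0.004,
    charring = function(l, amplitude, decay_nm = 200)
      amplitude * exp(-(l - 650) / decay_nm)),
    class = "chromophore_basis")
}

#' @export
as_tibble.chromophore_basis <- function(x, ...) {
  tibble::tibble(wavelength_nm = x$grid, hb = x$hb(x$grid),
                 hbo2 = x$hbo2(x$grid), methb = x$methb(x$grid),
                 water = x$water(x$grid))
}

#' Load a tabulated extinction spectrum as a basis function
#'
#' Reads a two-column delimited text table (wavelength_nm, value) and returns
#' a cubic-spline evaluable function, for swapping real extinction data into
#' [compose_absorption()].
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field separator.
#' @return A function of wavelength (nm).
#' @export
read_extinction_table <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(tab) < 2) stop("expected two columns: wavelength, value")
  stats::splinefun(tab[[1]], tab[[2]], method = "natural")
}

#' Tissue optical state
#'
#' A snapshot of the chromophore and scattering state of the tissue:
#' heme-species concentrations, water volume fraction with its spectral
#' shift/width modifiers, the Hb band shift, the Mie power-law scattering
#' parameters and the charring amplitude.
#'
#' @param c_hb,c_hbo2,c_methb Chromophore concentrations (unitless
#'   multipliers of the basis spectra, >= 0).
#' @param water_fraction Water volume fraction in `[0, 1]`.
#' @param water_shift_nm Signed shift of the water band (negative =
#'   blueshift).
#' @param water_width_factor Width multiplier of the water band (< 1 =
#'   narrowing).
#' @param hb_shift_nm Signed shift of the Hb spectrum (positive = redshift).
#' @param a,b Mie power-law parameters: `mus'(lambda) = a (lambda/650)^-b`,
#'   `a` in 1/cm.
#' @param charring_amp Charring absorption amplitude at 650 nm, 1/cm.
#' @param temperature_C Tissue temperature.
#' @return A `tissue_state`.
#' @export
tissue_state <- function(c_hb = 0.55, c_hbo2 = 0.25, c_methb = 0,
                         water_fraction = 0.75, water_shift_nm = 0,
                         water_width_factor = 1, hb_shift_nm = 0,
                         a = 6.9, b = 1.2, charring_amp = 0,
                         temperature_C = 23) {
  stopifnot(c_hb >= 0, c_hbo2 >= 0, c_methb >= 0,
            water_fraction >= 0, water_fraction <= 1,
            water_width_factor > 0, a > 0, charring_amp >= 0)
  structure(list(c_hb = c_hb, c_hbo2 = c_hbo2, c_methb = c_methb,
                 water_fraction = water_fraction,
                 water_shift_nm = water_shift_nm,
                 water_width_factor = water_width_factor,
                 hb_shift_nm = hb_shift_nm, a = a, b = b,
                 charring_amp = charring_amp,
                 temperature_C = temperature_C),
            class = "tissue_state")
}

#' @export
print.tissue_state <- function(x, ...) {
  cat(sprintf(
    "<tissue_state> %g C: Hb %.3g, HbO2 %.3g, metHb %.3g, water %.2f (d %.1f nm, w %.2f), a %.3g, b %.3g, char %.3g\n",
    x$temperature_C, x$c_hb, x$c_hbo2, x$c_methb, x$water_fraction,
    x$water_shift_nm, x$water_width_factor, x$a, x$b, x$charring_amp))
  invisible(x)
}

#' Compose the absorption spectrum of a tissue state
#'
#' Additive chromophore model:
#' `mua(lambda) = c_hb * hb(lambda - hb_shift) + c_hbo2 * hbo2 + c_methb *
#' methb + water_fraction * water(lambda; shift, width) + charring(lambda)`.
#' Linear in all concentrations and non-negative.
#'
#' @param state A [tissue_state()].
#' @param basis A [default_basis()].
#' @param grid Optional wavelength grid override, nm.
#' @return Tibble with `wavelength_nm`, `mua_cm1`.
#' @export
compose_absorption <- function(state, basis = default_basis(), grid = NULL) {
  stopifnot(inherits(state, "tissue_state"),
            inherits(basis, "chromophore_basis"))
  l <- if (is.null(grid)) basis$grid else grid
  mua <- state$c_hb * basis$hb(l - state$hb_shift_nm) +
    state$c_hbo2 * basis$hbo2(l) +
    state$c_methb * basis$methb(l) +
    state$water_fraction * basis$water(l, state$water_shift_nm,
                                       state$water_width_factor) +
    basis$charring(l, state$charring_amp)
  tibble::tibble(wavelength_nm = l, mua_cm1 = pmax(mua, 0))
}

#' Reduced scattering spectrum of a tissue state
#'
#' @param state A [tissue_state()].
#' @param grid Wavelength grid, nm.
#' @param lambda0_nm Power-law reference wavelength.
#' @return Tibble with `wavelength_nm`, `musp_cm1`.
#' @export
compose_scattering <- function(state, grid = seq(650, 1100, 10),
                               lambda0_nm = 650) {
  tibble::tibble(wavelength_nm = grid,
                 musp_cm1 = state$a * (grid / lambda0_nm)^(-state$b))
}

#' RF treatment protocol
#'
#' @param target_temp_C Target (tine) temperature: 70 (critical treatment)
#'   or 105 (over-treatment with charring); any value accepted.
#' @param ramp_s Linear heating ramp duration, s (slightly under three
#'   minutes in practice; default 180).
#' @param hold_s Treatment duration at the target temperature, s
#'   (default 600).
#' @param sampling `"broadband"` (full 650--1100 nm spectrum once per
#'   minute) or `"five_wavelength"` (770/840/910/980/1060 nm every 10 s).
#' @param cooling_s Passive cooling duration appended after the hold
#'   (0 = none).
#' @param cooling_tau_s Exponential cooling time constant toward room
#'   temperature (23 C).
#' @return A `treatment_protocol`.
#' @export
treatment_protocol <- function(target_temp_C = 105, ramp_s = 180,
                               hold_s = 600,
                               sampling = c("broadband", "five_wavelength"),
                               cooling_s = 0, cooling_tau_s = 240) {
  stopifnot(ramp_s > 0, hold_s > 0, cooling_s >= 0, cooling_tau_s > 0)
  structure(list(target_temp_C = target_temp_C, ramp_s = ramp_s,
                 hold_s = hold_s, sampling = match.arg(sampling),
                 cooling_s = cooling_s, cooling_tau_s = cooling_tau_s,
                 room_temp_C = 23),
            class = "treatment_protocol")
}

#' Temperature at a given time of the protocol
#'
#' Piecewise profile: linear ramp from room temperature to the target,
#' constant hold, optional exponential passive cooling back toward room
#' temperature.
#'
#' @param protocol A [treatment_protocol()].
#' @param t_s Time(s) from treatment start, s (vectorized).
#' @return Temperature(s) in Celsius.
#' @export
temperature_profile <- function(protocol, t_s) {
  stopifnot(all(t_s >= 0))
  p <- protocol
  end_hold <- p$ramp_s + p$hold_s
  ifelse(t_s <= p$ramp_s,
         p$room_temp_C + (p$target_temp_C - p$room_temp_C) * t_s / p$ramp_s,
         ifelse(t_s <= end_hold,
                p$target_temp_C,
                p$room_temp_C + (p$target_temp_C - p$room_temp_C) *
                  exp(-(t_s - end_hold) / p$cooling_tau_s)))
}

#' Kinetic parameters of the tissue trajectory
#'
#' Rates and thresholds governing how the tissue state evolves with the
#' thermal history. The functional forms (first-order methemoglobin
#' conversion above its threshold, exponential water loss scaled by
#' temperature excess, logistic scattering rise, linear charring growth
#' above its onset) are phenomenological choices; the thresholds are ordered
#' scattering onset < metHb threshold < charring onset. Defaults are tuned
#' to the myocardium-like magnitudes: scattering plateau gain 2x at a 70 C
#' target and 3x at 105 C, Hb redshift 4 / 15 nm, water blueshift -4 / -5 nm
#' with narrowing to 0.85 / 0.75 of the native width.
#'
#' @param scattering_onset_C,scattering_steepness_C Logistic onset and
#'   steepness of the scattering rise (denaturation), Celsius.
#' @param plateau_gain_70,plateau_gain_105 Scattering plateau gain at the
#'   two canonical targets; other targets interpolate linearly.
#' @param hold_drift_per_s Slow fractional scattering increase during the
#'   hold below the charring onset.
#' @param methb_threshold_C,methb_rate_per_s First-order Hb+HbO2 -> metHb
#'   conversion above the threshold.
#' @param hb_degradation_rate_per_s Chromophore degradation rate above 50 C.
#' @param water_loss_rate_per_s Water loss rate per unit temperature excess
#'   (scaled by `(T - 45) / 60`, clamped at 0).
#' @param temp_knots_C,hb_shift_knots_nm,water_shift_knots_nm,width_knots
#'   Piecewise-linear maps from the maximum temperature reached to the Hb
#'   redshift, water blueshift and water-band width factor.
#' @param b_shift_knots Piecewise-linear change of the power-law exponent b.
#' @param charring_onset_C,charring_rate_cm1_per_s,charring_decay_nm
#'   Charring absorption growth above onset and its spectral decay constant.
#' @param charring_musp_decline_per_s Exponential scattering decline rate
#'   while above the charring onset.
#' @param cooling_reversibility Named fractions (`water_shift`,
#'   `water_width`, `musp`) of each feature that reverts during passive
#'   cooling.
#' @return A `trajectory_params` list.
#' @export
trajectory_params <- function(scattering_onset_C = 58,
                              scattering_steepness_C = 4.5,
                              plateau_gain_70 = 2.0,
                              plateau_gain_105 = 3.0,
                              hold_drift_per_s = 1e-4,
                              methb_threshold_C = 75,
                              methb_rate_per_s = 1.5e-3,
                              hb_degradation_rate_per_s = 3e-4,
                              water_loss_rate_per_s = 1.5e-3,
                              temp_knots_C = c(23, 40, 70, 105),
                              hb_shift_knots_nm = c(0, 0, 4, 15),
                              water_shift_knots_nm = c(0, 0, -4, -5),
                              width_knots = c(1, 1, 0.85, 0.75),
                              b_shift_knots = c(0, 0, 0.2, 0),
                              charring_onset_C = 100,
                              charring_rate_cm1_per_s = 5e-4,
                              charring_decay_nm = 200,
                              charring_musp_decline_per_s = 8.4e-4,
                              cooling_reversibility = list(
                                water_shift = 0.3, water_width = 0.4,
                                musp = 0.05)) {
  stopifnot(scattering_onset_C < methb_threshold_C,
            methb_threshold_C < charring_onset_C)
  structure(as.list(environment()), class = "trajectory_params")
}

# Time spent above a temperature threshold up to time t (numeric dose
# integral on a 0.5 s grid; trajectories are slow relative to that).
dose_integral <- function(protocol, t_s, f, dt = 0.5) {
  if (t_s <= 0) return(0)
  tt <- seq(0, t_s, by = dt)
  temps <- temperature_profile(protocol, tt)
  sum(f(temps)) * dt
}

#' Evolve the tissue state along a treatment protocol
#'
#' Deterministic state trajectory: heme species degrade above 50 C and
#' convert to methemoglobin (first order) above 75 C; water is lost at a
#' rate scaling with temperature excess; the water band shifts blue and
#' narrows, and the Hb band shifts red, following the maximum temperature
#' reached; reduced scattering rises logistically with temperature to a
#' plateau gain set by the target (2x at 70 C, 3x at 105 C), drifts slowly
#' during the hold, and declines while above the charring onset; charring
#' absorption grows only above 100 C. During passive cooling the configured
#' fractions of the water shift, water width and scattering gain revert.
#'
#' @param params A [trajectory_params()].
#' @param protocol A [treatment_protocol()].
#' @param t_s Time from treatment start, s (scalar).
#' @param native Native [tissue_state()] at room temperature.
#' @return A [tissue_state()] at time `t_s`.
#' @export
evolve_state <- function(params, protocol, t_s, native = tissue_state()) {
  stopifnot(inherits(params, "trajectory_params"),
            inherits(protocol, "treatment_protocol"), t_s >= 0)
  p <- params
  Tnow <- temperature_profile(protocol, t_s)
  end_hold <- protocol$ramp_s + protocol$hold_s
  Tmax <- if (t_s <= protocol$ramp_s) Tnow else protocol$target_temp_C
  cool_prog <- if (t_s > end_hold)
    (protocol$target_temp_C - Tnow) /
      (protocol$target_temp_C - protocol$room_temp_C) else 0

  tau50 <- dose_integral(protocol, t_s, function(T) as.numeric(T > 50))
  tau_met <- dose_integral(protocol, t_s,
                           function(T) as.numeric(T > p$methb_threshold_C))
  tau_char <- dose_integral(protocol, t_s,
                            function(T) as.numeric(T > p$charring_onset_C))
  water_dose <- dose_integral(protocol, t_s,
                              function(T) pmax(0, (T - 45) / 60))
  hold_time <- dose_integral(
    protocol, t_s,
    function(T) as.numeric(T >= protocol$target_temp_C - 1e-9)) -
    tau_char

  deg <- exp(-p$hb_degradation_rate_per_s * tau50)
  f_met <- 1 - exp(-p$methb_rate_per_s * tau_met)

  map <- function(knots) stats::approx(p$temp_knots_C, knots, xout = Tmax,
                                       rule = 2)$y
  hb_shift <- map(p$hb_shift_knots_nm)
  water_shift <- map(p$water_shift_knots_nm) *
    (1 - p$cooling_reversibility$water_shift * cool_prog)
  width <- 1 - (1 - map(p$width_knots)) *
    (1 - p$cooling_reversibility$water_width * cool_prog)
  b_shift <- map(p$b_shift_knots)

  gain_target <- stats::approx(c(70, 105),
                               c(p$plateau_gain_70, p$plateau_gain_105),
                               xout = protocol$target_temp_C, rule = 2)$y
  g <- 1 + (gain_target - 1) /
    (1 + exp(-(Tnow - p$scattering_onset_C) / p$scattering_steepness_C))
  if (t_s > protocol$ramp_s)  # hold the heating-phase plateau when cooling
    g <- 1 + (gain_target - 1) /
      (1 + exp(-(protocol$target_temp_C - p$scattering_onset_C) /
                 p$scattering_steepness_C))
  g <- g * (1 + p$hold_drift_per_s * max(hold_time, 0)) *
    exp(-p$charring_musp_decline_per_s * tau_char) *
    (1 - p$cooling_reversibility$musp * cool_prog)

  tissue_state(
    c_hb = native$c_hb * deg * (1 - f_met),
    c_hbo2 = native$c_hbo2 * deg * (1 - f_met),
    c_methb = (native$c_hb + native$c_hbo2) * deg * f_met,
    water_fraction = native$water_fraction *
      exp(-p$water_loss_rate_per_s * water_dose),
    water_shift_nm = water_shift,
    water_width_factor = width,
    hb_shift_nm = hb_shift,
    a = native$a * g,
    b = native$b + b_shift,
    charring_amp = p$charring_rate_cm1_per_s * tau_char,
    temperature_C = Tnow)
}

#' Synthesize a full DTOF dataset along a treatment protocol
#'
#' For every timestamp and wavelength of the protocol's sampling mode, the
#' tissue state is evolved, its `(mua, mus')` composed, the forward model
#' evaluated (library interpolation, Beer-Lambert absorption, IRF
#' convolution) and Poisson counting noise added. Paired ground truth is
#' emitted for recovery testing. Fully reproducible given `seed`.
#'
#' @param params A [trajectory_params()].
#' @param protocol A [treatment_protocol()].
#' @param library An [build_library()] covering the trajectory's `mus'`
#'   range.
#' @param irf An `irf` on the library grid.
#' @param counts_per_curve Expected total counts per DTOF (default 1e6).
#' @param seed Integer seed (required).
#' @param basis A [default_basis()].
#' @param native Native [tissue_state()].
#' @param timestamps_s Optional override of the sampling timestamps.
#' @param n_replicates Number of replicate "samples" with inter-sample
#'   variability.
#' @param replicate_sd Log-scale standard deviation of the per-replicate
#'   concentration and scattering multipliers (default 0.03, keeping
#'   inter-sample deviation under 5%).
#' @return A list with `records` (list of `dtof`), `truth` (tibble of
#'   ground-truth `mua_cm1` / `musp_cm1` per replicate, timestamp and
#'   wavelength) and `states` (tibble of state variables per timestamp).
#' @export
generate_dataset <- function(params = trajectory_params(),
                             protocol = treatment_protocol(),
                             library, irf, counts_per_curve = 1e6, seed,
                             basis = default_basis(),
                             native = tissue_state(), timestamps_s = NULL,
                             n_replicates = 1, replicate_sd = 0.03) {
  if (missing(seed)) stop("`seed` is required for every stochastic operation")
  wavelengths <- if (protocol$sampling == "broadband")
    seq(650, 1100, 10) else c(770, 840, 910, 980, 1060)
  if (is.null(timestamps_s)) {
    timestamps_s <- if (protocol$sampling == "broadband")
      seq(0, 720, by = 60) else seq(0, 600, by = 10)
  }
  acq <- if (protocol$sampling == "broadband") 60 / length(wavelengths) else 1

  rep_factors <- local_seed_int(seed, {
    m <- matrix(exp(stats::rnorm(2 * n_replicates, 0, replicate_sd)),
                ncol = 2)
    m[1, ] <- 1  # first replicate is the nominal sample
    m
  })

  states <- purrr::map(timestamps_s, function(t)
    evolve_state(params, protocol, t, native))
  state_tbl <- dplyr::bind_rows(purrr::map2(timestamps_s, states, function(t, s)
    tibble::tibble(timestamp_s = t, temperature_C = s$temperature_C,
                   c_hb = s$c_hb, c_hbo2 = s$c_hbo2, c_methb = s$c_methb,
                   water_fraction = s$water_fraction,
                   water_shift_nm = s$water_shift_nm,
                   water_width_factor = s$water_width_factor,
                   hb_shift_nm = s$hb_shift_nm, a = s$a, b = s$b,
                   charring_amp = s$charring_amp)))

  records <- list()
  truth <- list()
  counter <- 0L
  for (r in seq_len(n_replicates)) {
    fa <- rep_factors[r, 1]; fs <- rep_factors[r, 2]
    for (it in seq_along(timestamps_s)) {
      st <- states[[it]]
      mua <- compose_absorption(st, basis, grid = wavelengths)$mua_cm1 * fa
      musp <- compose_scattering(st, grid = wavelengths)$musp_cm1 * fs
      rng <- library_range(library)
      if (any(musp < rng[1] | musp > rng[2]))
        stop(sprintf(
          "trajectory mus' range [%.3g, %.3g] exceeds library range [%.3g, %.3g]",
          min(musp), max(musp), rng[1], rng[2]))
      for (iw in seq_along(wavelengths)) {
        counter <- counter + 1L
        model <- convolve_irf(
          apply_absorption(interpolate_library(library, musp[iw]), mua[iw]),
          irf)
        rec <- add_counting_noise(
          model, total_counts = counts_per_curve,
          acquisition_time_s = acq, wavelength_nm = wavelengths[iw],
          timestamp_s = timestamps_s[it],
          seed = as.integer(seed) + counter)
        records[[counter]] <- rec
        truth[[counter]] <- tibble::tibble(
          replicate = r, timestamp_s = timestamps_s[it],
          wavelength_nm = wavelengths[iw],
          mua_cm1 = mua[iw], musp_cm1 = musp[iw])
      }
    }
  }
  list(records = records, truth = dplyr::bind_rows(truth),
       states = state_tbl, protocol = protocol, params = params)
}
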