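# Temporal point spread functions: the forward model's currency.

new_tpsf <- function(grid, values, geometry, mus_prime, mua = 0,
                     photons_launched = NA_real_, null_absorption = (mua == 0),
                     bookkeeping = NULL, convolved = FALSE) {
  stopifnot(inherits(grid, "time_grid"), length(values) == grid$n_bins,
            all(values >= 0))
  structure(
    list(grid = grid, values = as.numeric(values), geometry = geometry,
         mus_prime = mus_prime, mua = mua,
         photons_launched = photons_launched,
         null_absorption = isTRUE(null_absorption),
         bookkeeping = bookkeeping, convolved = isTRUE(convolved)),
    class = "tpsf")
}

#' @export
print.tpsf <- function(x, ...) {
  cat(sprintf(
    "<tpsf> mus' = %s /cm, mua = %g /cm, %d bins x %g ps, transmitted fraction %.3g%s\n",
    format(x$mus_prime), x$mua, x$grid$n_bins, x$grid$bin_width_ps,
    sum(x$values), if (x$null_absorption) " (null absorption)" else ""))
  invisible(x)
}

#' @export
as_tibble.tpsf <- function(x, ...) {
  tibble::tibble(time_ps = bin_centers(x$grid), value = x$values)
}

#' Simulate a null-absorption reference TPSF by Monte Carlo
#'
#' Runs a photon-transport Monte Carlo through a slab at the given reduced
#' scattering coefficient with zero absorption ("white" Monte Carlo).
#' Scattering is isotropic with `mus = mus_prime` (similarity relation:
#' only the reduced coefficient is identifiable from diffuse transmittance).
#' Unpolarized Fresnel reflection/refraction is applied at both faces;
#' internally reflected photons continue propagating. Each photon leaving the
#' exit face within the detector radius scores its exact exit time into the
#' histogram.
#'
#' @param geometry A [slab_geometry()].
#' @param mus_prime Reduced scattering coefficient, 1/cm (> 0).
#' @param grid A [time_grid()].
#' @param n_photons Photons to launch (>= 1e4 recommended).
#' @param seed Integer seed; the run is fully deterministic given it.
#' @param mua Absorption coefficient (1/cm). Default 0 (white Monte Carlo);
#'   positive values use continuous weight attenuation along the exact path,
#'   mainly for validating the Beer-Lambert factorization.
#' @param roulette_threshold Weight below which survival roulette triggers
#'   (0 disables; see Details).
#' @return A `tpsf` whose `values` are expected transmitted weight per bin
#'   per launched photon. `bookkeeping` holds the weight balance
#'   (transmitted/reflected/absorbed/late) for conservation checks.
#'   If no photon reaches the detector the result carries
#'   `bookkeeping$empty = TRUE` rather than failing silently.
#' @details Photon paths are truncated once their elapsed time exceeds the
#'   grid span; that truncated weight is accounted separately (`late_weight`).
#'   With the default grid this bounds path lengths, so weights stay far above
#'   any roulette threshold and roulette is off by default, which keeps
#'   same-seed runs with and without absorption on identical trajectories.
#' @examples
#' g <- slab_geometry()
#' tp <- simulate_reference_tpsf(g, mus_prime = 10, time_grid(512, 20),
#'                               n_photons = 1e4, seed = 1)
#' sum(tp$values)
#' @export
simulate_reference_tpsf <- function(geometry, mus_prime, grid = time_grid(),
                                    n_photons = 1e6, seed, mua = 0,
                                    roulette_threshold = 0) {
  stopifnot(inherits(geometry, "slab_geometry"), mus_prime > 0,
            n_photons >= 1, mua >= 0)
  if (missing(seed)) stop("`seed` is required for every stochastic operation")
  res <- .mc_slab_cpp(geometry$thickness_cm, geometry$n_sample,
                      geometry$n_external, geometry$detector_radius_cm,
                      mus = mus_prime, mua = mua,
                      t0 = grid$t0_ps, dt = grid$bin_width_ps,
                      n_bins = grid$n_bins,
                      n_photons = n_photons, seed = as.integer(seed),
                      roulette_threshold = roulette_threshold)
  bk <- res[c("detected_weight", "transmitted_weight", "reflected_weight",
              "absorbed_weight", "late_weight", "roulette_net_weight",
              "n_detected")]
  bk$empty <- res$n_detected == 0
  if (bk$empty)
    warning("no transmitted photon reached the detector; empty curve flagged")
  new_tpsf(grid, res$values, geometry, mus_prime, mua = mua,
           photons_launched = n_photons, null_absorption = (mua == 0),
           bookkeeping = bk)
}

#' Apply Beer-Lambert absorption to a TPSF
#'
#' Multiplies each bin by `exp(-mua * v * t)` with `v = c / n_sample`
#' evaluated at the bin centre: the white Monte Carlo absorption scaling that
#' converts a null-absorption reference curve into the curve for absorption
#' coefficient `mua`.
#'
#' @param tpsf A `tpsf`.
#' @param mua Absorption coefficient to add, 1/cm (>= 0).
#' @return A new `tpsf` with total absorption `tpsf$mua + mua`; the input is
#'   unchanged.
#' @examples
#' g <- slab_geometry()
#' tp <- da_transmittance(g, mua = 0, mus_prime = 10, time_grid(512, 20))
#' tp2 <- apply_absorption(tp, 0.1)
#' @export
apply_absorption <- function(tpsf, mua) {
  stopifnot(inherits(tpsf, "tpsf"))
  if (!is.numeric(mua) || length(mua) != 1 || is.na(mua) || mua < 0)
    stop("`mua` must be a single non-negative number")
  v <- C_VACUUM / tpsf$geometry$n_sample
  vals <- tpsf$values * exp(-mua * v * bin_centers(tpsf$grid))
  out <- tpsf
  out$values <- vals
  out$mua <- tpsf$mua + mua
  out$null_absorption <- out$mua == 0
  out
}

#' Rescale a TPSF using the scaling property of the radiative transfer equation
#'
#' The RTE is invariant under joint rescaling of all lengths by `k` and the
#' scattering coefficient by `1/k`: the transmittance curve for
#' `(k * L, mus' / k)` is the reference curve with its time axis stretched by
#' `k`. Per-bin transmitted fractions are preserved; bin widths scale with the
#' time axis.
#'
#' @param reference A null-absorption `tpsf`.
#' @param k Positive scale factor.
#' @return A `tpsf` on the rescaled grid with geometry lengths `* k` and
#'   `mus_prime / k`.
#' @export
scale_tpsf <- function(reference, k) {
  stopifnot(inherits(reference, "tpsf"), k > 0)
  if (!reference$null_absorption)
    stop("scale_tpsf() requires a null-absorption reference curve")
  g <- reference$grid
  new_grid <- time_grid(g$n_bins, g$bin_width_ps * k, g$t0_ps * k)
  geom <- reference$geometry
  new_geom <- slab_geometry(geom$thickness_cm * k, geom$n_sample,
                            geom$n_external, geom$detector_radius_cm * k)
  new_tpsf(new_grid, reference$values, new_geom, reference$mus_prime / k,
           mua = 0, photons_launched = reference$photons_launched,
           null_absorption = TRUE, bookkeeping = reference$bookkeeping)
}

# Resample a curve of per-bin masses onto another uniform grid (linear in
# density), clamping everything before the ballistic time to zero.
resample_tpsf_values <- function(values, from_grid, to_grid, t_ballistic = 0) {
  dens <- values / from_grid$bin_width_ps
  tc_from <- bin_centers(from_grid)
  tc_to <- bin_centers(to_grid)
  d <- stats::approx(tc_from, dens, xout = tc_to, rule = 1, yleft = 0,
                     yright = 0)$y
  d[is.na(d)] <- 0
  d[tc_to < t_ballistic] <- 0
  d * to_grid$bin_width_ps
}

#' Weighted mean transit time of a curve
#'
#' @param tpsf A `tpsf`, or numeric values with `grid` supplied.
#' @param grid Optional [time_grid()] when `tpsf` is a bare numeric vector.
#' @return Mean photon arrival time, ps.
#' @export
mean_transit_time <- function(tpsf, grid = NULL) {
  if (inherits(tpsf, "tpsf")) {
    vals <- tpsf$values
    grid <- tpsf$grid
  } else vals <- tpsf
  s <- sum(vals)
  if (s <= 0) return(NA_real_)
  sum(vals * bin_centers(grid)) / s
}
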