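# Closed-form diffusion-approximation transmittance: the analytic oracle the
# Monte Carlo forward model is validated against in the diffusive regime.

# Effective internal-reflection coefficient A for the extrapolated-boundary
# condition, from numerically integrated unpolarized Fresnel reflectance
# (valid for any index ratio, including n_sample < n_external).
boundary_A <- function(n_sample, n_external) {
  R_unpol <- function(theta) {
    cosi <- cos(theta)
    sint <- n_sample / n_external * sin(theta)
    R <- numeric(length(theta))
    tir <- sint >= 1
    R[tir] <- 1
    ok <- !tir
    cost <- sqrt(1 - sint[ok]^2)
    rs <- (n_sample * cosi[ok] - n_external * cost) /
          (n_sample * cosi[ok] + n_external * cost)
    rp <- (n_sample * cost - n_external * cosi[ok]) /
          (n_sample * cost + n_external * cosi[ok])
    R[ok] <- 0.5 * (rs^2 + rp^2)
    R
  }
  r_phi <- stats::integrate(function(th) 2 * sin(th) * cos(th) * R_unpol(th),
                            0, pi / 2, rel.tol = 1e-10)$value
  r_j <- stats::integrate(function(th) 3 * sin(th) * cos(th)^2 * R_unpol(th),
                          0, pi / 2, rel.tol = 1e-10)$value
  r_eff <- (r_phi + r_j) / (2 - r_phi + r_j)
  (1 + r_eff) / (1 - r_eff)
}

#' Diffusion-approximation time-resolved slab transmittance
#'
#' Analytic transmitted flux through a slab for a pencil beam, from the
#' diffusion approximation to the radiative transfer equation with
#' extrapolated-boundary conditions (infinite series of image sources).
#' The lateral photon spread is integrated over the coaxial detector disk.
#' Serves as the closed-form oracle for the Monte Carlo transport model in
#' the diffusive regime (`mus_prime >> mua`); outside that regime the Monte
#' Carlo fit is the method of record and this solution is only indicative.
#'
#' @param geometry A [slab_geometry()].
#' @param mua Absorption coefficient, 1/cm (>= 0).
#' @param mus_prime Reduced scattering coefficient, 1/cm (> 0).
#' @param grid A [time_grid()].
#' @param n_images Number of image-source pairs on each side (default 8;
#'   fully converged for slabs a few transport lengths thick).
#' @return A `tpsf` with per-bin transmitted weight. Absorption enters only
#'   through the Beer-Lambert factor, so
#'   `da_transmittance(geom, mua, ...)` equals
#'   `apply_absorption(da_transmittance(geom, 0, ...), mua)` bin-wise.
#' @examples
#' tp <- da_transmittance(slab_geometry(), 0.05, 10, time_grid(1024, 10))
#' @export
da_transmittance <- function(geometry, mua, mus_prime, grid = time_grid(),
                             n_images = 8) {
  stopifnot(inherits(geometry, "slab_geometry"), mua >= 0, mus_prime > 0)
  if (mus_prime < 10 * mua)
    warning("mus_prime is not >> mua: outside the diffusive regime, ",
            "the diffusion approximation may be inaccurate")
  L <- geometry$thickness_cm
  v <- C_VACUUM / geometry$n_sample
  D <- 1 / (3 * mus_prime)
  z0 <- 1 / mus_prime
  ze <- 2 * boundary_A(geometry$n_sample, geometry$n_external) * D
  tc <- bin_centers(grid)
  tt <- pmax(tc, .Machine$double.eps)
  Dvt4 <- 4 * D * v * tt

  flux <- numeric(length(tc))
  period <- 2 * (L + 2 * ze)
  for (m in -n_images:n_images) {
    zp <- m * period + z0                 # positive image of the source
    zn <- m * period - 2 * ze - z0        # negative image
    flux <- flux +
      (L - zp) * exp(-(L - zp)^2 / Dvt4) -
      (L - zn) * exp(-(L - zn)^2 / Dvt4)
  }
  # z-dimension Green's function only: the lateral gaussian is integrated
  # over the detector disk (the `disk` factor below)
  pref <- v * (4 * pi * D * v * tt)^(-1 / 2) / (2 * v * tt)
  disk <- 1 - exp(-geometry$detector_radius_cm^2 / Dvt4)
  vals <- pref * flux * disk * exp(-mua * v * tt) * grid$bin_width_ps
  vals[vals < 0] <- 0
  vals[tc <= 0] <- 0
  new_tpsf(grid, vals, geometry, mus_prime, mua = mua,
           null_absorption = (mua == 0))
}
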