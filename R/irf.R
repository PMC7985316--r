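# Instrument model: IRF synthesis, convolution, photon-counting noise.

new_irf <- function(grid, values, fwhm_ps, peak_position_ps,
                    wavelength_nm = NA_real_) {
  stopifnot(inherits(grid, "time_grid"), length(values) == grid$n_bins,
            all(values >= 0), sum(values) > 0)
  structure(list(grid = grid, values = as.numeric(values), fwhm_ps = fwhm_ps,
                 peak_position_ps = peak_position_ps,
                 wavelength_nm = wavelength_nm),
            class = "irf")
}

#' @export
print.irf <- function(x, ...) {
  cat(sprintf("<irf> FWHM %.1f ps, peak at %.1f ps, area %.4g\n",
              x$fwhm_ps, x$peak_position_ps, sum(x$values)))
  invisible(x)
}

#' @export
as_tibble.irf <- function(x, ...) {
  tibble::tibble(time_ps = bin_centers(x$grid), value = x$values)
}

# FWHM of a sampled unimodal curve by linear interpolation of the half-max
# crossings. Returns NA if the half level is not crossed on both sides.
curve_fwhm <- function(t, y) {
  pk <- which.max(y)
  half <- y[pk] / 2
  left <- NA_real_; right <- NA_real_
  if (pk > 1) {
    below <- which(y[1:(pk - 1)] <= half)
    if (length(below)) {
      i <- max(below)
      left <- t[i] + (half - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
    }
  }
  if (pk < length(y)) {
    below <- which(y[(pk + 1):length(y)] <= half)
    if (length(below)) {
      j <- pk + min(below)
      right <- t[j - 1] + (half - y[j - 1]) / (y[j] - y[j - 1]) * (t[j] - t[j - 1])
    }
  }
  right - left
}

#' Synthesize an instrument response function
#'
#' Generates a unit-area IRF of the requested full width at half maximum on a
#' time grid. The real instrument's IRF shape is detector specific; a
#' gaussian is the default stand-in, and an exponentially modified gaussian
#' is offered because silicon-photomultiplier responses carry a diffusion
#' tail.
#'
#' @param fwhm_ps Full width at half maximum, ps (>= 2 bin widths, < grid
#'   span). Default 80 ps, representative of a sub-90 ps TCSPC chain.
#' @param grid A [time_grid()].
#' @param shape `"gaussian"` or `"emg"` (exponentially modified gaussian).
#' @param peak_position_ps Position of the gaussian centre, ps.
#' @param tail_ps Exponential tail constant for `shape = "emg"`, ps.
#' @param wavelength_nm Optional wavelength tag.
#' @return An `irf`, normalized to unit area, whose measured FWHM is within
#'   one bin of the request (for the gaussian shape).
#' @examples
#' irf <- synthesize_irf(80, time_grid(1024, 2.5), peak_position_ps = 500)
#' @export
synthesize_irf <- function(fwhm_ps = 80, grid = time_grid(),
                           shape = c("gaussian", "emg"),
                           peak_position_ps = 500, tail_ps = 100,
                           wavelength_nm = NA_real_) {
  shape <- match.arg(shape)
  span <- grid$n_bins * grid$bin_width_ps
  if (fwhm_ps < 2 * grid$bin_width_ps)
    stop("fwhm_ps below two bin widths cannot be represented on this grid")
  if (fwhm_ps >= span) stop("fwhm_ps exceeds the grid span")
  tc <- bin_centers(grid)
  sigma <- fwhm_ps / (2 * sqrt(2 * log(2)))
  vals <- switch(shape,
    gaussian = stats::dnorm(tc, peak_position_ps, sigma),
    emg = {
      # gaussian (mu, sigma) convolved with exp tail of constant tau
      tau <- tail_ps
      lam <- 1 / tau
      arg <- lam / 2 * (2 * peak_position_ps + lam * sigma^2 - 2 * tc)
      z <- (peak_position_ps + lam * sigma^2 - tc) / (sqrt(2) * sigma)
      lam / 2 * exp(pmin(arg, 700)) * erfc_(z)
    })
  vals[vals < 0] <- 0
  vals <- vals / sum(vals)
  measured <- curve_fwhm(tc, vals)
  new_irf(grid, vals, fwhm_ps = measured,
          peak_position_ps = tc[which.max(vals)],
          wavelength_nm = wavelength_nm)
}

erfc_ <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

#' Convolve a model TPSF with the instrument response
#'
#' Discrete linear convolution truncated to the common time grid, computed by
#' the direct sum. The measurement chain applies the instrument blur after
#' the medium's response, so absorption must be applied to the TPSF *before*
#' convolution; convolution and the Beer-Lambert factor do not commute.
#'
#' @param model A `tpsf` (or numeric vector on the same grid).
#' @param irf An `irf` on the identical [time_grid()].
#' @return A `tpsf`-classed curve of expected counts shape; total area equals
#'   `area(model) * area(irf)` up to truncation at the grid end.
#' @export
convolve_irf <- function(model, irf) {
  stopifnot(inherits(irf, "irf"))
  if (inherits(model, "tpsf")) {
    if (!same_grid(model$grid, irf$grid))
      stop("model and IRF must share the same time grid")
    vals <- .conv_direct_cpp(model$values, irf$values)
    # the convolution is relative to the grid origin: shift by t0 bins if any
    out <- model
    out$values <- pmax(vals, 0)
    out$convolved <- TRUE
    out
  } else {
    stopifnot(length(model) == irf$grid$n_bins)
    .conv_direct_cpp(as.numeric(model), irf$values)
  }
}

#' Add photon-counting (Poisson) noise to an expected curve
#'
#' Scales the expected shape to a total number of detected photons, adds a
#' uniform background rate, and draws independent Poisson counts per bin --
#' the TCSPC statistics of a DTOF measurement.
#'
#' @param expected A `tpsf` (typically IRF-convolved) or numeric vector of
#'   expected shape.
#' @param grid [time_grid()] (taken from `expected` when it is a `tpsf`).
#' @param total_counts Expected total signal counts (> 0).
#' @param background_rate Background counts per second spread uniformly over
#'   the grid (dark counts).
#' @param acquisition_time_s Acquisition time, s.
#' @param wavelength_nm Wavelength tag, nm.
#' @param timestamp_s Seconds from treatment start.
#' @param seed Integer seed (required).
#' @return A `dtof` record: integer counts per bin plus acquisition metadata.
#' @export
add_counting_noise <- function(expected, total_counts, background_rate = 0,
                               acquisition_time_s = 1, wavelength_nm = NA_real_,
                               timestamp_s = 0, seed, grid = NULL) {
  if (missing(seed)) stop("`seed` is required for every stochastic operation")
  stopifnot(total_counts > 0, background_rate >= 0, acquisition_time_s > 0)
  if (inherits(expected, "tpsf")) {
    grid <- expected$grid
    shape <- expected$values
  } else shape <- as.numeric(expected)
  stopifnot(!is.null(grid), length(shape) == grid$n_bins)
  s <- sum(shape)
  if (s <= 0) stop("expected curve has zero area")
  lambda <- shape / s * total_counts +
    background_rate * acquisition_time_s / grid$n_bins
  counts <- local_seed_int(seed, stats::rpois(length(lambda), lambda))
  new_dtof(grid, counts, wavelength_nm = wavelength_nm,
           acquisition_time_s = acquisition_time_s, timestamp_s = timestamp_s,
           background_rate = background_rate)
}

# Evaluate `expr` under a temporary R RNG state seeded with `seed`,
# restoring the caller's state afterwards.
local_seed_int <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

new_dtof <- function(grid, counts, wavelength_nm, acquisition_time_s = 1,
                     timestamp_s = 0, background_rate = 0) {
  counts <- as.integer(round(counts))
  stopifnot(inherits(grid, "time_grid"), length(counts) == grid$n_bins,
            all(counts >= 0))
  structure(list(grid = grid, counts = counts,
                 wavelength_nm = wavelength_nm,
                 acquisition_time_s = acquisition_time_s,
                 timestamp_s = timestamp_s,
                 background_rate = background_rate),
            class = "dtof")
}

#' @export
print.dtof <- function(x, ...) {
  cat(sprintf("<dtof> %snm, t = %gs, %d bins, %d counts\n",
              if (is.na(x$wavelength_nm)) "? " else paste0(x$wavelength_nm, " "),
              x$timestamp_s, x$grid$n_bins, sum(x$counts)))
  invisible(x)
}

#' @export
as_tibble.dtof <- function(x, ...) {
  tibble::tibble(time_ps = bin_centers(x$grid), counts = x$counts)
}
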