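# Inverse problem: recover (mua, mus') per wavelength by fitting
# IRF-convolved, library-interpolated model curves to measured DTOFs.

#' Fitting configuration
#'
#' @param rise_fraction Rising-edge threshold of the fit window as a fraction
#'   of the curve maximum. Default 0.80.
#' @param fall_fraction Falling-edge threshold. Default 0.01. Must satisfy
#'   `0 < fall_fraction < rise_fraction < 1`.
#' @param objective `"poisson-deviance"` (counts are Poisson; default) or
#'   `"weighted-least-squares"`.
#' @param max_iterations Optimizer iteration cap.
#' @param reltol Relative convergence tolerance on the objective.
#' @param mua_init Coarse-scan absorption values, 1/cm.
#' @param background `"prepeak"` estimates a constant background from the
#'   first 5% of bins and subtracts it; `"none"` disables.
#' @param uncertainties Compute curvature-based parameter uncertainties.
#' @return A `fit_config` list.
#' @export
fit_config <- function(rise_fraction = 0.80, fall_fraction = 0.01,
                       objective = c("poisson-deviance",
                                     "weighted-least-squares"),
                       max_iterations = 500, reltol = 1e-8,
                       mua_init = exp(seq(log(0.002), log(2), length.out = 9)),
                       background = c("prepeak", "none"),
                       uncertainties = TRUE) {
  stopifnot(fall_fraction > 0, rise_fraction < 1,
            fall_fraction < rise_fraction)
  structure(list(rise_fraction = rise_fraction,
                 fall_fraction = fall_fraction,
                 objective = match.arg(objective),
                 max_iterations = max_iterations, reltol = reltol,
                 mua_init = mua_init,
                 background = match.arg(background),
                 uncertainties = isTRUE(uncertainties)),
            class = "fit_config")
}

#' Locate the fit window of a counts curve
#'
#' The fit uses the part of the temporal curve with counts above 80% of the
#' maximum on the rising edge and above 1% on the falling edge (both
#' thresholds relative, hence amplitude invariant and configurable).
#'
#' @param counts Numeric vector of (background-subtracted) counts.
#' @param config A [fit_config()].
#' @return Integer vector `c(start, end)`, 1-based inclusive bin indices.
#' @examples
#' fit_window(c(0, 100, 800, 1000, 600, 300, 50, 9, 0)) # c(3, 7)
#' @export
fit_window <- function(counts, config = fit_config()) {
  if (all(counts <= 0) || max(counts) == min(counts))
    stop("curve is flat or empty: no fit window")
  pk <- which.max(counts)
  lo <- config$rise_fraction * counts[pk]
  hi <- config$fall_fraction * counts[pk]
  start <- min(which(counts[1:pk] >= lo))
  end <- pk - 1 + max(which(counts[pk:length(counts)] >= hi))
  c(start = start, end = end)
}

# Model curve for a parameter pair, on the library grid.
model_counts <- function(mua, mus_prime, irf, library) {
  ref <- interpolate_library(library, mus_prime)
  convolve_irf(apply_absorption(ref, mua), irf)$values
}

objective_value <- function(model, data, window, objective) {
  i <- window[1]:window[2]
  m <- model[i]; d <- data[i]
  if (all(m <= 0)) return(list(value = Inf, amplitude = NA_real_))
  if (objective == "poisson-deviance") {
    A <- sum(d) / sum(m)                      # Poisson MLE of the free scale
    mm <- pmax(A * m, 1e-12)
    dev <- 2 * sum(ifelse(d > 0, d * log(d / mm) - (d - mm), mm))
    list(value = dev, amplitude = A)
  } else {
    w <- pmax(d, 1)                           # var(counts) ~ counts
    A <- sum(d * m / w) / sum(m^2 / w)
    list(value = sum((d - A * m)^2 / w), amplitude = A)
  }
}

#' Fit optical properties to a single DTOF
#'
#' Minimizes the configured objective over absorption, reduced scattering and
#' a free multiplicative amplitude, with the model
#' `amplitude * convolve_irf(apply_absorption(interpolate_library(mus'), mua), irf)`
#' evaluated only inside the fit window of the measured curve. The amplitude
#' is always free: time-domain fitting relies on the temporal shape of the
#' DTOF only, never on its absolute intensity, which makes the recovery
#' immune to coupling and power fluctuations. A coarse scan over library
#' nodes and a grid of absorption values seeds a Nelder-Mead refinement in
#' `(log mus', log mua)`.
#'
#' @param record A `dtof` (or numeric counts vector on the library grid).
#' @param irf An `irf` on the same grid.
#' @param library An [build_library()] result covering the search range.
#' @param config A [fit_config()].
#' @return An `od_fit` with elements `mua`, `mus_prime`, `amplitude`,
#'   `objective`, `window`, `converged`, `boundary`, optional `mua_err` /
#'   `musp_err`, and the background estimate. Non-convergence is flagged,
#'   never silent; a solution at the library edge is flagged `boundary`.
#' @export
fit_optical_properties <- function(record, irf, library,
                                   config = fit_config()) {
  if (inherits(record, "dtof")) {
    if (!same_grid(record$grid, irf$grid))
      stop("record and IRF must share the same time grid")
    counts <- as.numeric(record$counts)
  } else counts <- as.numeric(record)
  if (!same_grid(library$grid, irf$grid))
    stop("library and IRF must share the same time grid")

  bg <- 0
  if (config$background == "prepeak") {
    # median over the earliest bins: robust against the convolution's rising
    # edge leaking into the pre-peak region
    nbg <- max(1L, floor(0.05 * length(counts)))
    bg <- stats::median(counts[seq_len(nbg)])
  }
  d <- pmax(counts - bg, 0)
  window <- fit_window(d, config)

  mg <- library$mus_grid
  rng <- range(mg)
  # coarse scan over library nodes plus segment midpoints: the library
  # interpolation is exact at nodes but piecewise between them, which leaves
  # shallow ridges at segment boundaries; seeding inside segments keeps the
  # refinement out of neighbouring basins
  scan_nodes <- if (length(mg) > 13)
    mg[unique(round(seq(1, length(mg), length.out = 13)))] else mg
  if (length(scan_nodes) > 1) {
    mids <- sqrt(scan_nodes[-1] * scan_nodes[-length(scan_nodes)])
    scan_nodes <- sort(c(scan_nodes, mids))
  }
  best <- list(value = Inf)
  for (ms in scan_nodes) for (ma in config$mua_init) {
    ob <- objective_value(model_counts(ma, ms, irf, library), d, window,
                          config$objective)
    if (ob$value < best$value) best <- c(ob, list(mua = ma, mus = ms))
  }
  # the deviance valley is narrow in mua: profile mua by 1-D minimization at
  # the scan winner and its neighbours before the 2-D refinement
  ib <- which.min(abs(scan_nodes - best$mus))
  for (ms in scan_nodes[max(1, ib - 2):min(length(scan_nodes), ib + 2)]) {
    o1 <- stats::optimize(function(lma)
      objective_value(model_counts(exp(lma), ms, irf, library), d, window,
                      config$objective)$value,
      interval = log(c(1e-5, 5)), tol = 1e-3)
    if (o1$objective < best$value)
      best <- list(value = o1$objective, mua = exp(o1$minimum), mus = ms)
  }

  lo_mua <- 1e-5
  pen <- function(p) {
    ms <- exp(p[2]); ma <- exp(p[1])
    penalty <- 0
    if (ms < rng[1]) { penalty <- penalty + 1e8 * (log(rng[1]) - p[2])^2; ms <- rng[1] }
    if (ms > rng[2]) { penalty <- penalty + 1e8 * (p[2] - log(rng[2]))^2; ms <- rng[2] }
    ob <- objective_value(model_counts(ma, ms, irf, library), d, window,
                          config$objective)
    ob$value + penalty
  }
  # Nelder-Mead with restarts: the deviance valley is narrow and curved in
  # (log mua, log mus'), and a single simplex pass can stall on the
  # residual Monte Carlo roughness of the library surface.
  p0 <- c(log(max(best$mua, lo_mua)), log(best$mus))
  opt <- stats::optim(p0, pen, method = "Nelder-Mead",
                      control = list(maxit = config$max_iterations,
                                     reltol = config$reltol))
  stalled <- FALSE
  for (restart in 1:6) {
    opt2 <- stats::optim(opt$par, pen, method = "Nelder-Mead",
                         control = list(maxit = config$max_iterations,
                                        reltol = config$reltol))
    improved <- opt$value - opt2$value >
      config$reltol * (abs(opt$value) + 1e-8)
    opt <- opt2
    if (!improved) { stalled <- TRUE; break }
  }
  mua_hat <- exp(opt$par[1])
  mus_hat <- min(max(exp(opt$par[2]), rng[1]), rng[2])
  fin <- objective_value(model_counts(mua_hat, mus_hat, irf, library), d,
                         window, config$objective)
  boundary <- mus_hat <= rng[1] * (1 + 1e-6) || mus_hat >= rng[2] * (1 - 1e-6)

  mua_err <- musp_err <- NA_real_
  if (config$uncertainties && is.finite(fin$value)) {
    errs <- try(curvature_errors(pen, opt$par, config$objective), silent = TRUE)
    if (!inherits(errs, "try-error")) {
      mua_err <- errs[1] * mua_hat    # delta method from log scale
      musp_err <- errs[2] * mus_hat
    }
  }
  structure(list(mua = mua_hat, mus_prime = mus_hat,
                 amplitude = fin$amplitude, objective = fin$value,
                 objective_kind = config$objective,
                 window = window,
                 converged = opt$convergence == 0 || stalled,
                 boundary = boundary, background = bg,
                 mua_err = mua_err, musp_err = musp_err,
                 wavelength_nm = if (inherits(record, "dtof"))
                   record$wavelength_nm else NA_real_,
                 timestamp_s = if (inherits(record, "dtof"))
                   record$timestamp_s else NA_real_),
            class = "od_fit")
}

# Curvature (observed-information) standard errors on the log-parameter
# scale, from a finite-difference Hessian of half the deviance.
curvature_errors <- function(fn, par, objective) {
  h <- 1e-3
  H <- matrix(0, 2, 2)
  f0 <- fn(par)
  for (i in 1:2) for (j in i:2) {
    ei <- ej <- c(0, 0); ei[i] <- h; ej[j] <- h
    H[i, j] <- H[j, i] <-
      (fn(par + ei + ej) - fn(par + ei) - fn(par + ej) + f0) / h^2
  }
  H <- H / 2  # half-deviance ~ negative log-likelihood
  V <- solve(H)
  sqrt(pmax(diag(V), 0))
}

#' @export
print.od_fit <- function(x, ...) {
  cat(sprintf(
    "<od_fit> mua = %.4g /cm, mus' = %.4g /cm (amplitude %.3g)%s%s\n",
    x$mua, x$mus_prime, x$amplitude,
    if (!x$converged) " [NOT CONVERGED]" else "",
    if (x$boundary) " [library boundary]" else ""))
  invisible(x)
}

#' @export
tidy.od_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mua", "mus_prime", "amplitude"),
    estimate = c(x$mua, x$mus_prime, x$amplitude),
    std.error = c(x$mua_err, x$musp_err, NA_real_))
}

#' @export
glance.od_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, objective_kind = x$objective_kind,
                 converged = x$converged, boundary = x$boundary,
                 window_start = x$window[1], window_end = x$window[2])
}

#' Fit a broadband optical-property spectrum
#'
#' Runs [fit_optical_properties()] independently at each wavelength and
#' assembles the recovered absorption and reduced scattering spectra.
#' Failed wavelengths are kept as missing rows, never interpolated over.
#'
#' @param records List of `dtof` records, one per wavelength.
#' @param irfs A single `irf` used for all wavelengths, or a list parallel
#'   to `records`.
#' @param library An `mc_library`.
#' @param config A [fit_config()].
#' @return A tibble of class `optical_spectrum` with columns
#'   `wavelength_nm`, `mua_cm1`, `musp_cm1`, `mua_err`, `musp_err`,
#'   `amplitude`, `converged`, `boundary`, `timestamp_s`, sorted by
#'   wavelength.
#' @export
fit_spectrum <- function(records, irfs, library, config = fit_config()) {
  if (length(records) == 0) stop("no records supplied")
  if (inherits(irfs, "irf")) irfs <- rep(list(irfs), length(records))
  stopifnot(length(irfs) == length(records))
  rows <- purrr::map2(records, irfs, function(rec, irf) {
    fit <- try(fit_optical_properties(rec, irf, library, config),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      tibble::tibble(wavelength_nm = rec$wavelength_nm, mua_cm1 = NA_real_,
                     musp_cm1 = NA_real_, mua_err = NA_real_,
                     musp_err = NA_real_, amplitude = NA_real_,
                     converged = FALSE, boundary = NA,
                     timestamp_s = rec$timestamp_s)
    } else {
      tibble::tibble(wavelength_nm = rec$wavelength_nm, mua_cm1 = fit$mua,
                     musp_cm1 = fit$mus_prime, mua_err = fit$mua_err,
                     musp_err = fit$musp_err, amplitude = fit$amplitude,
                     converged = fit$converged, boundary = fit$boundary,
                     timestamp_s = rec$timestamp_s)
    }
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$wavelength_nm)
  class(out) <- c("optical_spectrum", class(out))
  out
}

as_optical_spectrum <- function(df) {
  stopifnot(all(c("wavelength_nm") %in% names(df)))
  if (!inherits(df, "optical_spectrum"))
    class(df) <- c("optical_spectrum", class(df))
  df
}
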