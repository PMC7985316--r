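# Quantification of treatment signatures from recovered spectra: power-law
# scattering parameters, spline-based peak localization and shifts,
# per-wavelength paired significance testing, normalized time courses.

#' Fit the Mie power law to a reduced scattering spectrum
#'
#' Fits `mus'(lambda) = a * (lambda / lambda0)^(-b)` by least squares on the
#' log-log scale: `a = exp(intercept)` is the reduced scattering at the
#' reference wavelength (tracking the density of scattering centres) and
#' `b = -slope` tracks their effective size.
#'
#' @param spectrum A data frame with `wavelength_nm` and `musp_cm1` columns
#'   (an `optical_spectrum` works as is).
#' @param lambda0_nm Reference wavelength, nm. Default 650.
#' @return A `power_law_fit` with elements `a`, `b`, `lambda0_nm`,
#'   `residual_norm`, `n`; has [generics::tidy()] and [generics::glance()]
#'   methods.
#' @examples
#' sp <- tibble::tibble(wavelength_nm = seq(650, 1100, 10),
#'                      musp_cm1 = 6.9 * (wavelength_nm / 650)^-1.2)
#' fit_power_law(sp)
#' @export
fit_power_law <- function(spectrum, lambda0_nm = 650) {
  stopifnot(all(c("wavelength_nm", "musp_cm1") %in% names(spectrum)))
  ok <- is.finite(spectrum$musp_cm1) & spectrum$musp_cm1 > 0
  if (any(is.finite(spectrum$musp_cm1) & spectrum$musp_cm1 <= 0))
    warning("non-positive reduced scattering values excluded from the fit")
  if (sum(ok) < 5)
    stop("need at least 5 valid wavelengths for the power-law fit")
  x <- log(spectrum$wavelength_nm[ok] / lambda0_nm)
  y <- log(spectrum$musp_cm1[ok])
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  structure(list(a = unname(exp(co[1])), b = unname(-co[2]),
                 lambda0_nm = lambda0_nm,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 n = sum(ok), lm = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> a = %.3g /cm at %g nm, b = %.3g (n = %d)\n",
              x$a, x$lambda0_nm, x$b, x$n))
  invisible(x)
}

#' @export
tidy.power_law_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble::tibble(term = c("a", "b"),
                 estimate = c(x$a, x$b),
                 std.error = c(x$a * s[1, 2], s[2, 2]))
}

#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(lambda0_nm = x$lambda0_nm, residual_norm = x$residual_norm,
                 r.squared = summary(x$lm)$r.squared, n = x$n)
}

#' Locate a spectral peak (or valley) by cubic spline interpolation
#'
#' Spectra sampled every 10 nm still carry sub-grid peak information: a
#' natural cubic spline through the sampled points is evaluated on a 0.1 nm
#' grid inside the requested band and its extremum located. This is how
#' shifts of a few nm are quantified from 10 nm sampling.
#'
#' @param spectrum Data frame with `wavelength_nm` and the value column.
#' @param band Length-2 numeric, nm: the search band (must contain at least
#'   4 sample points).
#' @param mode `"maximum"` or `"minimum"`.
#' @param value_col Column holding the spectral values. Default `"mua_cm1"`.
#' @param eval_step_nm Evaluation grid step. Default 0.1 nm.
#' @return A `peak_estimate`: `peak_lambda_nm`, `peak_value`, `fwhm_nm`
#'   (half-prominence width above the band-edge baseline; `NA` if the
#'   half level is not crossed inside the band), `at_edge` flag.
#' @export
locate_peak <- function(spectrum, band, mode = c("maximum", "minimum"),
                        value_col = "mua_cm1", eval_step_nm = 0.1) {
  mode <- match.arg(mode)
  stopifnot(length(band) == 2, band[1] < band[2])
  wl <- spectrum$wavelength_nm
  y <- spectrum[[value_col]]
  ok <- is.finite(y)
  wl <- wl[ok]; y <- y[ok]
  if (sum(wl >= band[1] & wl <= band[2]) < 4)
    stop("band must contain at least 4 sampled wavelengths")
  sp <- stats::splinefun(wl, y, method = "natural")
  lam <- seq(max(band[1], min(wl)), min(band[2], max(wl)), by = eval_step_nm)
  fy <- sp(lam)
  if (mode == "minimum") fy <- -fy
  i <- which.max(fy)
  at_edge <- i == 1 || i == length(lam)
  if (at_edge)
    warning("extremum lies at the band edge: not an interior peak")
  peak_lambda <- lam[i]
  peak_value <- sp(peak_lambda)

  fwhm <- NA_real_
  if (!at_edge && mode == "maximum") {
    base <- mean(c(sp(lam[1]), sp(lam[length(lam)])))
    half <- base + (peak_value - base) / 2
    left <- right <- NA_real_
    yy <- sp(lam)
    lo <- which(lam < peak_lambda & yy <= half)
    hi <- which(lam > peak_lambda & yy <= half)
    if (length(lo)) left <- lam[max(lo)]
    if (length(hi)) right <- lam[min(hi)]
    fwhm <- right - left
  }
  structure(list(band = band, mode = mode, peak_lambda_nm = peak_lambda,
                 peak_value = peak_value, fwhm_nm = fwhm, at_edge = at_edge),
            class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat(sprintf("<peak_estimate> %s at %.1f nm (value %.4g, FWHM %s nm)%s\n",
              x$mode, x$peak_lambda_nm, x$peak_value,
              ifelse(is.na(x$fwhm_nm), "NA", sprintf("%.1f", x$fwhm_nm)),
              if (x$at_edge) " [at band edge]" else ""))
  invisible(x)
}

#' Signed spectral shift of a peak between two spectra
#'
#' Locates the same band's extremum in a native and a treated spectrum and
#' reports the signed difference (positive = redshift, negative = blueshift).
#'
#' @param native,treated Data frames sharing the wavelength grid.
#' @param band,mode,value_col As in [locate_peak()].
#' @return A one-row tibble: `native_peak_nm`, `treated_peak_nm`, `shift_nm`,
#'   `native_fwhm_nm`, `treated_fwhm_nm`.
#' @export
peak_shift <- function(native, treated, band, mode = "maximum",
                       value_col = "mua_cm1") {
  stopifnot(isTRUE(all.equal(native$wavelength_nm, treated$wavelength_nm)))
  pn <- locate_peak(native, band, mode, value_col)
  pt <- locate_peak(treated, band, mode, value_col)
  tibble::tibble(native_peak_nm = pn$peak_lambda_nm,
                 treated_peak_nm = pt$peak_lambda_nm,
                 shift_nm = pt$peak_lambda_nm - pn$peak_lambda_nm,
                 native_fwhm_nm = pn$fwhm_nm,
                 treated_fwhm_nm = pt$fwhm_nm)
}

#' Per-wavelength paired t-test between replicate spectra
#'
#' Two-sided paired t-test at every wavelength between native and treated
#' replicate spectra (paired by sample index), flagging significance at
#' `p < alpha`. No multiple-testing correction is applied by default,
#' matching common practice for per-wavelength significance stars; a
#' Benjamini-Hochberg adjustment is available.
#'
#' @param native,treated Lists of paired replicate spectra (data frames
#'   sharing a wavelength grid), or numeric matrices
#'   (wavelength x replicate).
#' @param alpha Significance level. Default 0.05.
#' @param value_col Value column when spectra are data frames.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble: `wavelength_nm`, `mean_diff`, `statistic`, `df`,
#'   `p_value`, `significant`, `degenerate`. Zero-variance differences give
#'   `p = 0` if the mean difference is nonzero, else `p = 1`, flagged
#'   `degenerate`.
#' @export
per_wavelength_ttest <- function(native, treated, alpha = 0.05,
                                 value_col = "mua_cm1",
                                 adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  to_mat <- function(x) {
    if (is.matrix(x)) return(list(wl = seq_len(nrow(x)), m = x))
    stopifnot(is.list(x), length(x) >= 2)
    wl <- x[[1]]$wavelength_nm
    m <- vapply(x, function(sp) {
      stopifnot(isTRUE(all.equal(sp$wavelength_nm, wl)))
      sp[[value_col]]
    }, numeric(length(wl)))
    list(wl = wl, m = m)
  }
  a <- to_mat(native); b <- to_mat(treated)
  stopifnot(identical(dim(a$m), dim(b$m)))
  n <- ncol(a$m)
  if (n < 2) stop("need at least 2 paired replicates")
  d <- b$m - a$m
  mean_d <- rowMeans(d)
  sd_d <- apply(d, 1, stats::sd)
  df <- n - 1
  tstat <- mean_d / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- sd_d == 0
  p[degenerate & mean_d != 0] <- 0
  p[degenerate & mean_d == 0] <- 1
  tstat[degenerate] <- NA_real_
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  tibble::tibble(wavelength_nm = a$wl, mean_diff = mean_d, statistic = tstat,
                 df = df, p_value = p, significant = p < alpha,
                 degenerate = degenerate)
}

#' Normalize per-wavelength kinetic series to their initial values
#'
#' Divides every channel (wavelength x property) by its value at the first
#' timestamp, the standard presentation for treatment kinetics: all channels
#' start at 1 and the trace shows the relative evolution.
#'
#' @param series Long-format data frame with columns `timestamp_s`,
#'   `wavelength_nm`, and one or more value columns (default `mua_cm1`,
#'   `musp_cm1`).
#' @param value_cols Columns to normalize.
#' @return A tibble of class `timecourse` with the value columns replaced by
#'   their normalized versions. Channels with a zero initial value are set
#'   to `NA` and flagged in the `valid` column.
#' @export
normalize_timecourse <- function(series,
                                 value_cols = intersect(
                                   c("mua_cm1", "musp_cm1"), names(series))) {
  stopifnot(all(c("timestamp_s", "wavelength_nm") %in% names(series)),
            length(value_cols) >= 1)
  out <- series |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::arrange(.data$timestamp_s, .by_group = TRUE) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(value_cols),
      function(v) {
        v0 <- v[1]
        if (!is.finite(v0) || v0 == 0) rep(NA_real_, length(v)) else v / v0
      })) |>
    dplyr::ungroup()
  out$valid <- stats::complete.cases(out[value_cols])
  class(out) <- c("timecourse", class(out))
  out
}

#' Default spectral bands for the treatment signatures
#'
#' Bands for the deoxyhemoglobin peak, the emerging 840 nm peak, the 910 nm
#' valley and the water peak, all configurable.
#'
#' @return Named list of length-2 numeric bands (nm).
#' @export
default_bands <- function() {
  list(hb = c(720, 800), peak840 = c(810, 870), valley910 = c(880, 940),
       water = c(940, 1010))
}

#' Detect the optical signatures of thermal treatment
#'
#' Compares a treated spectrum with its native counterpart and reports, for
#' each signature of RF thermal treatment, a boolean and a signed magnitude:
#'
#' 1. absorption decrease above 900 nm (tissue dehydration);
#' 2. global reduced-scattering change (protein denaturation);
#' 3. emergence of a peak around 840 nm absent in the native spectrum
#'    (methemoglobin formation);
#' 4. redshift of the 760 nm deoxyhemoglobin peak;
#' 5. blueshift and narrowing of the 970 nm water peak;
#' 6. short-wavelength (650--800 nm) absorption increase (charring plus
#'    methemoglobin, over-treatment only);
#' 7. reduced scattering lower than after critical treatment (carbonization;
#'    needs the `critical` reference spectrum).
#'
#' Swapping `native` and `treated` negates the signed magnitudes.
#'
#' @param native,treated `optical_spectrum` data frames on a shared grid.
#' @param critical Optional spectrum of the critically treated (70 C) state
#'   for signature 7; `NA` when absent.
#' @param bands Band list as from [default_bands()].
#' @param rel_tol Minimum relative change treated as a real effect
#'   (default 0.05, i.e. beyond replicate-level variability).
#' @param shift_tol_nm Minimum shift treated as real (default 1 nm, the
#'   spline localization accuracy).
#' @return A tibble with one row per signature: `signature`, `detected`,
#'   `magnitude`, `units`, `description`.
#' @export
detect_signatures <- function(native, treated, critical = NULL,
                              bands = default_bands(), rel_tol = 0.05,
                              shift_tol_nm = 1) {
  stopifnot(isTRUE(all.equal(native$wavelength_nm, treated$wavelength_nm)))
  wl <- native$wavelength_nm

  # log-ratio of band means: symmetric, so swapping the spectra negates it
  rel_change <- function(sel, col) {
    a <- mean(native[[col]][sel], na.rm = TRUE)
    b <- mean(treated[[col]][sel], na.rm = TRUE)
    log(b / a)
  }
  # 1: absorption decrease beyond 900 nm
  d_nir <- rel_change(wl > 900, "mua_cm1")
  # 2: global scattering change
  d_sc <- rel_change(rep(TRUE, length(wl)), "musp_cm1")
  # 3: 840 nm peak emergence (interior local max present only in treated)
  prominence <- function(sp) {
    pk <- try(suppressWarnings(locate_peak(sp, bands$peak840)), silent = TRUE)
    if (inherits(pk, "try-error") || pk$at_edge) return(0)
    edges <- stats::splinefun(sp$wavelength_nm, sp$mua_cm1,
                              method = "natural")(bands$peak840)
    max(pk$peak_value - max(edges), 0)
  }
  prom_nat <- prominence(native); prom_trt <- prominence(treated)
  m840 <- prom_trt - prom_nat
  # 4: Hb redshift
  s_hb <- peak_shift(native, treated, bands$hb)
  # 5: water blueshift + narrowing
  s_w <- peak_shift(native, treated, bands$water)
  narrowed <- is.finite(s_w$native_fwhm_nm) && is.finite(s_w$treated_fwhm_nm) &&
    s_w$treated_fwhm_nm < s_w$native_fwhm_nm
  # 6: short-wavelength absorption rise
  d_short <- rel_change(wl >= 650 & wl <= 800, "mua_cm1")
  # 7: scattering below the critically treated state
  if (!is.null(critical)) {
    d_vs_crit <- log(mean(treated$musp_cm1, na.rm = TRUE) /
                       mean(critical$musp_cm1, na.rm = TRUE))
    det7 <- d_vs_crit < -rel_tol
  } else {
    d_vs_crit <- NA_real_; det7 <- NA
  }

  tibble::tibble(
    signature = c("mua_decrease_nir", "musp_change", "peak840_emergence",
                  "hb_redshift", "water_blueshift_narrowing",
                  "mua_increase_short", "musp_below_critical"),
    detected = c(d_nir < -rel_tol,
                 abs(d_sc) > rel_tol,
                 prom_trt > 0.01 && prom_nat < 0.2 * prom_trt,
                 s_hb$shift_nm > shift_tol_nm,
                 s_w$shift_nm < -shift_tol_nm && narrowed,
                 d_short > rel_tol,
                 det7),
    magnitude = c(d_nir, d_sc, m840, s_hb$shift_nm, s_w$shift_nm,
                  d_short, d_vs_crit),
    units = c("relative", "relative", "1/cm", "nm", "nm", "relative",
              "relative"),
    description = c(
      "log-ratio of mean absorption above 900 nm",
      "log-ratio of mean reduced scattering, full band",
      "840 nm band prominence gained by treatment",
      "signed shift of the 760 nm deoxyhemoglobin peak",
      "signed shift of the 970 nm water peak (with narrowing)",
      "log-ratio of mean absorption 650-800 nm",
      "log-ratio of reduced scattering vs critical treatment"))
}
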