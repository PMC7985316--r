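# ggplot2 displays for the pipeline's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   labs scale_y_log10 facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a time-of-flight curve
#'
#' @param object A `tpsf`, `irf` or `dtof`.
#' @param log_y Log-scale the count axis (default TRUE, the standard TCSPC
#'   display).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tpsf <- function(object, log_y = TRUE, ...) {
  df <- as_tibble(object)
  p <- ggplot(df[df$value > 0 | !log_y, ], aes(x = .data$time_ps, y = .data$value)) +
    geom_line() +
    labs(x = "time (ps)", y = "transmitted weight / bin")
  if (log_y) p <- p + scale_y_log10()
  p
}

#' @rdname autoplot.tpsf
#' @export
autoplot.irf <- function(object, log_y = TRUE, ...) {
  df <- as_tibble(object)
  p <- ggplot(df[df$value > 0 | !log_y, ], aes(x = .data$time_ps, y = .data$value)) +
    geom_line() + labs(x = "time (ps)", y = "IRF weight / bin")
  if (log_y) p <- p + scale_y_log10()
  p
}

#' @rdname autoplot.tpsf
#' @export
autoplot.dtof <- function(object, log_y = TRUE, ...) {
  df <- as_tibble(object)
  p <- ggplot(df[df$counts > 0 | !log_y, ], aes(x = .data$time_ps, y = .data$counts)) +
    geom_point(size = 0.3) + labs(x = "time (ps)", y = "counts / bin")
  if (log_y) p <- p + scale_y_log10()
  p
}

#' Plot an optical-property spectrum
#'
#' Absorption and reduced scattering vs wavelength, with error ribbons when
#' per-wavelength uncertainties are present.
#'
#' @param object An `optical_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot faceted by property.
#' @export
autoplot.optical_spectrum <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("wavelength_nm", "mua_cm1", "musp_cm1",
                                intersect(c("mua_err", "musp_err"),
                                          names(object)))],
    cols = c("mua_cm1", "musp_cm1"),
    names_to = "property", values_to = "value")
  long$err <- ifelse(long$property == "mua_cm1",
                     long$mua_err %||% NA_real_,
                     long$musp_err %||% NA_real_)
  p <- ggplot(long, aes(x = .data$wavelength_nm, y = .data$value)) +
    facet_wrap(~property, scales = "free_y",
               labeller = ggplot2::as_labeller(
                 c(mua_cm1 = "absorption (1/cm)",
                   musp_cm1 = "reduced scattering (1/cm)"))) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "wavelength (nm)", y = NULL)
  if (any(is.finite(long$err)))
    p <- p + geom_ribbon(aes(ymin = .data$value - .data$err,
                             ymax = .data$value + .data$err), alpha = 0.25)
  p
}

#' Plot a normalized kinetic time course
#'
#' @param object A `timecourse` tibble from [normalize_timecourse()].
#' @param ... Unused.
#' @return A ggplot, one facet per property, colored by wavelength.
#' @export
autoplot.timecourse <- function(object, ...) {
  value_cols <- intersect(c("mua_cm1", "musp_cm1"), names(object))
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::all_of(value_cols),
                              names_to = "property", values_to = "value")
  ggplot(long, aes(x = .data$timestamp_s, y = .data$value,
                   color = factor(.data$wavelength_nm))) +
    geom_line() + facet_wrap(~property, scales = "free_y") +
    labs(x = "time (s)", y = "normalized value", color = "wavelength (nm)")
}
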