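# Shared I/O: DTOF / IRF delimited-text files with a commented JSON header,
# optical-spectrum CSVs, and run-configuration validation.

dtof_header <- function(meta) {
  paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
}

parse_header <- function(line, path) {
  if (!startsWith(line, "# "))
    stop(sprintf("%s:1: expected a '# {json}' header line", path))
  jsonlite::fromJSON(sub("^# ", "", line))
}

#' Read and write DTOF histogram files
#'
#' A DTOF file is two-column delimited text (`time_ps`, `counts`) preceded
#' by one commented JSON header line carrying the acquisition metadata
#' (wavelength, acquisition time, timestamp, background rate, time grid).
#' The round trip is lossless: counts are integers and grid parameters are
#' serialized at full precision.
#'
#' @param record A `dtof` (for writing).
#' @param path File path.
#' @return `read_dtof()` returns a `dtof`; `write_dtof()` returns `path`
#'   invisibly. Malformed files are rejected with the offending line number.
#' @export
write_dtof <- function(record, path) {
  stopifnot(inherits(record, "dtof"))
  g <- record$grid
  meta <- list(type = "dtof", wavelength_nm = record$wavelength_nm,
               acquisition_time_s = record$acquisition_time_s,
               timestamp_s = record$timestamp_s,
               background_rate = record$background_rate,
               n_bins = g$n_bins, bin_width_ps = g$bin_width_ps,
               t0_ps = g$t0_ps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(dtof_header(meta), con)
  writeLines("time_ps\tcounts", con)
  writeLines(sprintf("%.10g\t%d", bin_centers(g), record$counts), con)
  invisible(path)
}

#' @rdname write_dtof
#' @export
read_dtof <- function(path) {
  lines <- readLines(path)
  meta <- parse_header(lines[1], path)
  if (!identical(meta$type, "dtof"))
    stop(sprintf("%s:1: not a dtof header", path))
  for (field in c("wavelength_nm", "n_bins", "bin_width_ps", "t0_ps"))
    if (is.null(meta[[field]]))
      stop(sprintf("%s:1: header missing '%s'", path, field))
  body <- lines[-(1:2)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad_cols <- which(lengths(parts) != 2)
  if (length(bad_cols))
    stop(sprintf("%s:%d: expected two tab-separated fields", path,
                 bad_cols[1] + 2L))
  counts <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts))
  if (length(bad))
    stop(sprintf("%s:%d: counts must be non-negative integers", path,
                 bad[1] + 2L))
  g <- time_grid(meta$n_bins, meta$bin_width_ps, meta$t0_ps)
  if (length(counts) != g$n_bins)
    stop(sprintf("%s: %d data rows but header declares %d bins", path,
                 length(counts), g$n_bins))
  new_dtof(g, counts, wavelength_nm = meta$wavelength_nm,
           acquisition_time_s = meta$acquisition_time_s %||% 1,
           timestamp_s = meta$timestamp_s %||% 0,
           background_rate = meta$background_rate %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write IRF files
#'
#' Same dialect as [write_dtof()] with real-valued weights instead of
#' integer counts.
#'
#' @param irf An `irf` (for writing).
#' @param path File path.
#' @return `read_irf()` returns an `irf`; `write_irf()` returns `path`
#'   invisibly.
#' @export
write_irf <- function(irf, path) {
  stopifnot(inherits(irf, "irf"))
  g <- irf$grid
  meta <- list(type = "irf", wavelength_nm = irf$wavelength_nm,
               fwhm_ps = irf$fwhm_ps, peak_position_ps = irf$peak_position_ps,
               n_bins = g$n_bins, bin_width_ps = g$bin_width_ps,
               t0_ps = g$t0_ps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(dtof_header(meta), con)
  writeLines("time_ps\tvalue", con)
  writeLines(sprintf("%.10g\t%.17g", bin_centers(g), irf$values), con)
  invisible(path)
}

#' @rdname write_irf
#' @export
read_irf <- function(path) {
  lines <- readLines(path)
  meta <- parse_header(lines[1], path)
  if (!identical(meta$type, "irf"))
    stop(sprintf("%s:1: not an irf header", path))
  vals <- as.numeric(vapply(strsplit(lines[-(1:2)], "\t", fixed = TRUE),
                            `[[`, "", 2))
  g <- time_grid(meta$n_bins, meta$bin_width_ps, meta$t0_ps)
  new_irf(g, vals, fwhm_ps = meta$fwhm_ps,
          peak_position_ps = meta$peak_position_ps,
          wavelength_nm = meta$wavelength_nm %||% NA_real_)
}

#' Read and write optical spectrum CSVs
#'
#' Columns `wavelength_nm`, `mua_cm1`, `musp_cm1`, `mua_err`, `musp_err`
#' (plus any extra columns present). Wavelengths must be strictly
#' increasing.
#'
#' @param spectrum A data frame (an `optical_spectrum` works as is).
#' @param path File path.
#' @return `read_spectrum()` returns an `optical_spectrum` tibble;
#'   `write_spectrum()` returns `path` invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  need <- c("wavelength_nm", "mua_cm1", "musp_cm1")
  miss <- setdiff(need, names(spectrum))
  if (length(miss)) stop("spectrum lacks columns: ", paste(miss, collapse = ", "))
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "mua_cm1", "musp_cm1")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing required columns: ", paste(miss, collapse = ", "))
  if (any(diff(df$wavelength_nm) <= 0))
    stop(path, ": wavelengths must be strictly increasing")
  as_optical_spectrum(tibble::as_tibble(df))
}

#' Validate a run configuration
#'
#' Checks a nested configuration list (typically parsed from YAML or JSON)
#' against the known block/key schema before any stage runs; unknown keys
#' are rejected so typos cannot silently fall back to defaults.
#'
#' @param config Named list with any of the blocks `geometry`, `library`,
#'   `fit`, `features`, `simulate`, `output`.
#' @return The validated config, invisibly.
#' @export
validate_config <- function(config) {
  schema <- list(
    geometry = c("thickness_cm", "n_sample", "n_external",
                 "detector_radius_cm"),
    library = c("mus_min", "mus_max", "n_nodes", "n_photons", "seed",
                "cache_path", "n_bins", "bin_width_ps"),
    fit = c("rise_fraction", "fall_fraction", "objective", "max_iterations",
            "reltol", "background", "uncertainties"),
    features = c("alpha", "bands", "lambda0_nm", "adjust"),
    simulate = c("target_temp_C", "ramp_s", "hold_s", "sampling",
                 "counts_per_curve", "seed", "n_replicates", "replicate_sd",
                 "irf_fwhm_ps"),
    output = c("directory", "log_level"))
  if (!is.list(config)) stop("config must be a named list")
  unknown_blocks <- setdiff(names(config), names(schema))
  if (length(unknown_blocks))
    stop("unknown config block(s): ", paste(unknown_blocks, collapse = ", "))
  for (blk in names(config)) {
    unknown <- setdiff(names(config[[blk]]), schema[[blk]])
    if (length(unknown))
      stop(sprintf("unknown key(s) in '%s': %s", blk,
                   paste(unknown, collapse = ", ")))
  }
  invisible(config)
}
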