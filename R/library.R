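# Monte Carlo reference library: null-absorption TPSFs on a grid of reduced
# scattering values, interpolated continuously in log(mus') for fitting.

#' Default reduced-scattering grid for a Monte Carlo library
#'
#' Geometrically spaced nodes; curve shape varies smoothly in `log(mus')`,
#' so geometric spacing gives near-uniform interpolation error.
#'
#' @param from,to Range of reduced scattering values, 1/cm.
#' @param n Number of nodes.
#' @return Numeric vector of nodes.
#' @export
default_mus_grid <- function(from = 1, to = 70, n = 25) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Build a Monte Carlo reference library
#'
#' Simulates one null-absorption reference TPSF per reduced-scattering grid
#' node. The library is the forward model's lookup table: queries between
#' nodes go through [interpolate_library()], absorption is added analytically
#' with [apply_absorption()].
#'
#' @param geometry A [slab_geometry()].
#' @param grid_mus_prime Strictly increasing reduced-scattering nodes, 1/cm.
#' @param grid A [time_grid()] shared by all curves.
#' @param n_photons Photons per curve.
#' @param seed Integer seed; node `i` uses `seed + i - 1`, so a rebuild with
#'   the same seed is bit-identical.
#' @return An object of class `mc_library`.
#' @examples
#' lib <- build_library(slab_geometry(), c(8, 12), time_grid(512, 20),
#'                      n_photons = 2e4, seed = 7)
#' @export
build_library <- function(geometry, grid_mus_prime = default_mus_grid(),
                          grid = time_grid(), n_photons = 1e6, seed) {
  if (missing(seed)) stop("`seed` is required")
  stopifnot(length(grid_mus_prime) >= 1,
            all(diff(grid_mus_prime) > 0), all(grid_mus_prime > 0))
  if (length(grid_mus_prime) > 1 &&
      max(diff(log(grid_mus_prime))) > log(2))
    warning("scattering grid is sparse (adjacent nodes differ by more than ",
            "a factor 2); interpolation error may exceed tolerance")
  curves <- vector("list", length(grid_mus_prime))
  for (i in seq_along(grid_mus_prime)) {
    curves[[i]] <- simulate_reference_tpsf(
      geometry, grid_mus_prime[i], grid, n_photons,
      seed = as.integer(seed) + i - 1L)
  }
  structure(
    list(geometry = geometry, grid = grid, mus_grid = grid_mus_prime,
         curves = curves,
         meta = list(n_photons = n_photons, seed = as.integer(seed))),
    class = "mc_library")
}

#' @export
print.mc_library <- function(x, ...) {
  cat(sprintf(
    "<mc_library> %d nodes, mus' in [%.3g, %.3g] /cm, %g photons/curve, seed %d\n",
    length(x$mus_grid), min(x$mus_grid), max(x$mus_grid),
    x$meta$n_photons, x$meta$seed))
  invisible(x)
}

#' Library range
#' @param library An `mc_library`.
#' @return Length-2 numeric: min and max reduced scattering covered.
#' @export
library_range <- function(library) range(library$mus_grid)

#' Interpolate a Monte Carlo library at an arbitrary reduced scattering value
#'
#' Exact at grid nodes. Between nodes, each bracketing curve is area
#' normalized and rescaled in time to the (log-linearly interpolated) mean
#' transit time of the query, the rescaled shapes are mixed linearly in
#' `log(mus')`, and the total transmitted fraction is interpolated
#' log-linearly. Mean transit time is therefore monotone between nodes.
#'
#' @param library An `mc_library`.
#' @param mus_prime Query value, 1/cm; must lie inside the library range
#'   (no extrapolation).
#' @return A null-absorption `tpsf` on the library's time grid.
#' @export
interpolate_library <- function(library, mus_prime) {
  stopifnot(inherits(library, "mc_library"))
  mg <- library$mus_grid
  tol <- 1e-9 * max(mg)
  if (mus_prime < min(mg) - tol || mus_prime > max(mg) + tol)
    stop(sprintf(
      "mus_prime = %g /cm outside library range [%g, %g]; no extrapolation",
      mus_prime, min(mg), max(mg)))
  mus_prime <- min(max(mus_prime, min(mg)), max(mg))
  hit <- which(abs(mg - mus_prime) < 1e-12 * mus_prime)
  if (length(hit)) return(library$curves[[hit[1]]])

  i <- findInterval(mus_prime, mg)
  c1 <- library$curves[[i]]; c2 <- library$curves[[i + 1]]
  w <- (log(mus_prime) - log(mg[i])) / (log(mg[i + 1]) - log(mg[i]))
  t1 <- mean_transit_time(c1); t2 <- mean_transit_time(c2)
  tq <- exp((1 - w) * log(t1) + w * log(t2))
  tb <- ballistic_time_ps(library$geometry)

  # rescale each node shape (unit area) so its mean lands on tq, then mix
  shift_shape <- function(cv, tm) {
    k <- tq / tm
    # density g(t) = f(t / k) / k on the same grid
    tc <- bin_centers(library$grid)
    dens <- cv$values / sum(cv$values) / library$grid$bin_width_ps
    g <- stats::approx(tc * k, dens / k, xout = tc, rule = 1,
                       yleft = 0, yright = 0)$y
    g[is.na(g)] <- 0
    g[tc < tb] <- 0
    g * library$grid$bin_width_ps
  }
  s1 <- shift_shape(c1, t1); s2 <- shift_shape(c2, t2)
  s1 <- s1 / max(sum(s1), .Machine$double.xmin)
  s2 <- s2 / max(sum(s2), .Machine$double.xmin)
  mix <- (1 - w) * s1 + w * s2
  Tq <- exp((1 - w) * log(sum(c1$values)) + w * log(sum(c2$values)))
  new_tpsf(library$grid, mix * Tq, library$geometry, mus_prime, mua = 0,
           photons_launched = library$meta$n_photons,
           null_absorption = TRUE)
}

#' Persist / reload a Monte Carlo library as delimited text plus a manifest
#'
#' The library is written as a directory containing `manifest.json`
#' (geometry, grids, seed, photon count, per-node bookkeeping) and
#' `curves.tsv` (bin centre time in ps, one column of per-bin weight per
#' node). The round trip is bit-exact: numbers are serialized at full
#' precision.
#'
#' @param library An `mc_library`.
#' @param path Directory to create/overwrite.
#' @return `write_library()` returns `path` invisibly; `read_library()`
#'   returns the reloaded `mc_library`.
#' @export
write_library <- function(library, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- library$geometry; tg <- library$grid
  manifest <- list(
    format = "rfaoptics-mc-library/1",
    geometry = unclass(g),
    time_grid = unclass(tg),
    mus_grid = library$mus_grid,
    n_photons = library$meta$n_photons,
    seed = library$meta$seed,
    bookkeeping = lapply(library$curves, function(cv) cv$bookkeeping))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  mat <- vapply(library$curves, function(cv) cv$values,
                numeric(tg$n_bins))
  df <- cbind(time_ps = bin_centers(tg), mat)
  colnames(df) <- c("time_ps", sprintf("node_%02d", seq_along(library$mus_grid)))
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     file.path(path, "curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "rfaoptics-mc-library/1"))
    stop("not an rfaoptics library manifest: ", path)
  g <- do.call(slab_geometry, as.list(manifest$geometry)[
    c("thickness_cm", "n_sample", "n_external", "detector_radius_cm")])
  tg <- time_grid(manifest$time_grid$n_bins, manifest$time_grid$bin_width_ps,
                  manifest$time_grid$t0_ps)
  tab <- utils::read.table(file.path(path, "curves.tsv"), header = TRUE,
                           sep = "\t")
  mus_grid <- as.numeric(manifest$mus_grid)
  bk <- manifest$bookkeeping
  curves <- lapply(seq_along(mus_grid), function(i) {
    new_tpsf(tg, tab[[i + 1]], g, mus_grid[i], mua = 0,
             photons_launched = manifest$n_photons, null_absorption = TRUE,
             bookkeeping = if (is.data.frame(bk)) as.list(bk[i, ]) else bk[[i]])
  })
  structure(
    list(geometry = g, grid = tg, mus_grid = mus_grid, curves = curves,
         meta = list(n_photons = manifest$n_photons,
                     seed = as.integer(manifest$seed))),
    class = "mc_library")
}
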