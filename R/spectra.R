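# Simulated Raman spectra.
#
# Each conformer's stick spectrum (scaled harmonic frequencies weighted by
# Raman activity) is broadened with unit-area Lorentzian profiles; the
# ensemble spectrum is the Boltzmann sum
#
#     B_T(nu) = sum_i N_i * W_i(nu)
#
# of the per-conformer spectra W_i on a shared wavenumber grid.  Intensities
# are in arbitrary units; activity controls the *integrated* intensity of a
# band because the Lorentzians have unit area.

#' Broadening and grid configuration for simulated spectra
#'
#' @param scaling_factor multiplicative harmonic-frequency correction applied
#'   before broadening; default 0.97, partially accounting for anharmonicity.
#'   Use 1.0 for inputs that are already scaled (never scale twice).
#' @param fwhm Lorentzian full width at half maximum, cm-1.  Not fixed by the
#'   underlying band-position analysis; default 10 cm-1, typical for
#'   condensed-phase Raman simulation.
#' @param grid_min,grid_max,grid_step wavenumber grid, cm-1 (defaults 400,
#'   4000, 1).  The amide I window 1600-1700 cm-1 is a view of this grid,
#'   not a truncation.
#' @return object of class `"broadening_config"`.
#' @export
broadening_config <- function(scaling_factor = 0.97, fwhm = 10,
                              grid_min = 400, grid_max = 4000,
                              grid_step = 1) {
  if (!is_number(scaling_factor) || scaling_factor <= 0 ||
      scaling_factor > 1.1)
    stop2("broadening_config: scaling_factor must be in (0, 1.1]")
  if (!is_number(fwhm) || fwhm <= 0)
    stop2("broadening_config: fwhm must be > 0")
  if (!is_number(grid_min) || !is_number(grid_max) || grid_min >= grid_max)
    stop2("broadening_config: need grid_min < grid_max")
  if (!is_number(grid_step) || grid_step <= 0)
    stop2("broadening_config: grid_step must be > 0")
  structure(
    list(scaling_factor = scaling_factor, fwhm = fwhm,
         grid_min = grid_min, grid_max = grid_max, grid_step = grid_step),
    class = "broadening_config"
  )
}

spectrum_grid <- function(config) {
  seq(config$grid_min, config$grid_max, by = config$grid_step)
}

#' Scale harmonic frequencies
#'
#' @param frequencies cm-1 (unscaled harmonic), or a [mode_table()].
#' @param scaling_factor dimensionless (> 0); 0.97 by default.
#' @return scaled frequencies, cm-1, order preserved.
#' @export
scale_frequencies <- function(frequencies, scaling_factor = 0.97) {
  if (is.data.frame(frequencies)) frequencies <- frequencies$frequency
  if (!is_number(scaling_factor) || scaling_factor <= 0)
    stop2("scale_frequencies: scaling_factor must be > 0")
  frequencies * scaling_factor
}

# unit-area Lorentzian centred at nu0 with full width at half maximum fwhm
lorentzian <- function(grid, nu0, fwhm) {
  hw <- fwhm / 2
  (hw / pi) / ((grid - nu0)^2 + hw^2)
}

new_raman_spectrum <- function(grid, intensity, metadata) {
  structure(list(grid = grid, intensity = intensity, metadata = metadata),
            class = "raman_spectrum")
}

#' Simulated Raman spectrum of a single conformer
#'
#' Scales every mode frequency, then sums activity-weighted unit-area
#' Lorentzians on the configured grid.  Modes whose centres fall outside the
#' grid window still contribute their tails.  An empty mode list yields the
#' all-zero spectrum.
#'
#' @param x a `"conformer"` or a [mode_table()].
#' @param config a [broadening_config()].
#' @return object of class `"raman_spectrum"`: list with `grid`, `intensity`
#'   (same length, arbitrary units >= 0) and `metadata`.
#' @export
conformer_spectrum <- function(x, config = broadening_config()) {
  modes <- if (inherits(x, "conformer")) x$modes else x
  grid <- spectrum_grid(config)
  intensity <- numeric(length(grid))
  centres <- scale_frequencies(modes$frequency, config$scaling_factor)
  for (k in seq_along(centres))
    intensity <- intensity +
      modes$raman_activity[k] * lorentzian(grid, centres[k], config$fwhm)
  new_raman_spectrum(
    grid, intensity,
    list(conformer = if (inherits(x, "conformer")) x$id else NA_character_,
         temperature = NA_real_,
         scaling_factor = config$scaling_factor, fwhm = config$fwhm)
  )
}

#' Boltzmann-summed ensemble Raman spectrum
#'
#' Pointwise convex combination `B_T(nu) = sum_i N_i W_i(nu)` of the
#' per-conformer spectra, all broadened on the shared configured grid.
#'
#' @param weighted a `"weighted_ensemble"`.
#' @param config a [broadening_config()].
#' @return a `"raman_spectrum"` with `metadata$conformer = "ensemble"`.
#' @export
ensemble_spectrum <- function(weighted, config = broadening_config()) {
  stopifnot(inherits(weighted, "weighted_ensemble"))
  grid <- spectrum_grid(config)
  total <- numeric(length(grid))
  for (i in seq_along(weighted$ensemble$conformers)) {
    wi <- conformer_spectrum(weighted$ensemble$conformers[[i]], config)
    if (length(wi$grid) != length(grid))
      stop2("ensemble_spectrum: conformer spectrum grid mismatch")
    total <- total + weighted$weights[i] * wi$intensity
  }
  new_raman_spectrum(
    grid, total,
    list(fragment = weighted$ensemble$fragment, conformer = "ensemble",
         temperature = weighted$temperature,
         scaling_factor = config$scaling_factor, fwhm = config$fwhm)
  )
}

#' Max-normalize a spectrum for plotting
#'
#' @param x a `"raman_spectrum"`.
#' @return the spectrum with peak intensity 1 (unchanged if all-zero).
#' @export
normalize_spectrum <- function(x) {
  m <- max(x$intensity)
  if (m > 0) x$intensity <- x$intensity / m
  x
}

#' Write a spectrum as two-column CSV with a JSON metadata sidecar
#'
#' @param x a `"raman_spectrum"`.
#' @param path CSV output path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(x, path) {
  utils::write.csv(data.frame(wavenumber = x$grid, intensity = x$intensity),
                   path, row.names = FALSE)
  jsonlite::write_json(x$metadata, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat("<raman_spectrum>", x$metadata$conformer %||% "?",
      sprintf("grid %g..%g cm-1 (%d points), max intensity %.4g\n",
              min(x$grid), max(x$grid), length(x$grid), max(x$intensity)))
  invisible(x)
}

#' Plot a simulated Raman spectrum
#'
#' Simple base-graphics line plot; overlay an experimental trace with
#' `lines()` if desired.
#'
#' @param x a `"raman_spectrum"`.
#' @param xlim wavenumber window, cm-1.
#' @param ... passed to [graphics::plot()].
#' @export
plot.raman_spectrum <- function(x, xlim = NULL, ...) {
  graphics::plot(x$grid, x$intensity, type = "l",
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "intensity (arb. units)", xlim = xlim, ...)
  invisible(x)
}
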