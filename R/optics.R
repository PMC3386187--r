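# X-ray optical constants and propagation geometry.

# hc in m * keV: lambda [m] = HC_KEV_M / E [keV]
HC_KEV_M <- 1.23984193e-9

#' Convert photon energy to X-ray wavelength
#'
#' @param energy photon energy in keV (positive).
#' @return wavelength in meters.
#' @examples
#' energy_to_wavelength(15) # ~8.27e-11 m
#' @export
energy_to_wavelength <- function(energy) {
  if (!is.numeric(energy) || any(!is.finite(energy)) || any(energy <= 0))
    stop_config("`energy` must be a positive photon energy in keV")
  HC_KEV_M / energy
}

#' Soft-tissue-like refractive index constants for the liver phantom
#'
#' Refractive index decrements (delta) and absorption indices (beta) at the
#' default 15 keV for the four phantom materials. Values are configurable
#' placeholders in the soft-tissue range (water-like delta ~1.2e-6 at 15 keV);
#' measured constants for mouse liver and hepatoma are not available.
#'
#' @return named list of `c(delta, beta)` per material.
#' @export
liver_materials <- function() {
  list(
    parenchyma = c(delta = 1.18e-6, beta = 1.10e-9),
    tumor      = c(delta = 1.26e-6, beta = 1.40e-9),
    necrosis   = c(delta = 1.05e-6, beta = 0.90e-9),
    vessel     = c(delta = 1.32e-6, beta = 1.60e-9)
  )
}

#' Optical constants for a monochromatic plane wave
#'
#' @param energy photon energy in keV.
#' @param materials named list of `c(delta, beta)` pairs (both >= 0).
#' @return an `optical_constants` object with fields `energy`, `wavelength`
#'   (m), `k` (wave number, 1/m) and `materials`.
#' @export
optical_constants <- function(energy = 15, materials = liver_materials()) {
  wavelength <- energy_to_wavelength(energy)
  for (nm in names(materials)) {
    mb <- materials[[nm]]
    if (length(mb) < 2L || any(!is.finite(mb[1:2])) || any(mb[1:2] < 0))
      stop_config("material '%s' must have finite delta, beta >= 0", nm)
  }
  structure(
    list(energy = energy, wavelength = wavelength,
         k = 2 * pi / wavelength, materials = materials),
    class = "optical_constants"
  )
}

#' Plane-wave propagation geometry
#'
#' @param distance sample-to-detector distance z in meters (>= 0).
#' @param pixel_size detector pixel pitch in meters.
#' @param grid_shape integer `c(rows, cols)`; both must be even (the Fourier
#'   and half-band wavelet grids require it).
#' @return a `propagation_geometry` object.
#' @export
propagation_geometry <- function(distance = 0.5, pixel_size = 9e-6,
                                 grid_shape = c(1024L, 1024L)) {
  if (!is.numeric(distance) || distance < 0)
    stop_config("`distance` must be >= 0 meters")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop_config("`pixel_size` must be > 0 meters")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 2L) ||
      any(grid_shape %% 2L != 0L))
    stop_config("`grid_shape` must be two even integers")
  structure(
    list(distance = distance, pixel_size = pixel_size,
         grid_shape = grid_shape),
    class = "propagation_geometry"
  )
}
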