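# Paraxial Fresnel propagation and the weak-object (TIE) intensity model.

#' Construct a wave field
#'
#' @param amplitude complex 2-D matrix of the field (unit incident amplitude).
#' @param pixel_size sampling pitch in meters.
#' @return a `wave_field` object.
#' @export
wave_field <- function(amplitude, pixel_size) {
  stopifnot(is.matrix(amplitude), is.numeric(pixel_size), pixel_size > 0)
  amplitude <- amplitude + 0i
  structure(list(amplitude = amplitude, pixel_size = pixel_size),
            class = "wave_field")
}

#' Exit wave of a projected phantom
#'
#' @param projection a `phantom_projection` (phase and contact intensity).
#' @return the object exit [wave_field()] `sqrt(I0) * exp(i * phi)`.
#' @export
projection_to_field <- function(projection) {
  stopifnot(inherits(projection, "phantom_projection"))
  wave_field(sqrt(projection$I0) * exp(1i * projection$phi),
             projection$pixel_size)
}

#' Free-space Fresnel propagation of a wave field
#'
#' Applies the paraxial transfer function
#' `H(u, v) = exp(i k z) * exp(-i pi lambda z (u^2 + v^2))`
#' in the spatial-frequency domain via the discrete Fourier transform on the
#' periodic grid. At `z = 0` the field is returned unchanged. If the chirp
#' phase wraps at the Nyquist frequency (`pi lambda z u_max^2 > pi`) a
#' warning reports the maximum alias-safe distance.
#'
#' @param field a [wave_field()].
#' @param geometry a [propagation_geometry()] whose grid matches the field.
#' @param optics an [optical_constants()] object (wavelength source).
#' @return the propagated [wave_field()].
#' @export
fresnel_propagate <- function(field, geometry, optics) {
  stopifnot(inherits(field, "wave_field"),
            inherits(geometry, "propagation_geometry"),
            inherits(optics, "optical_constants"))
  a <- field$amplitude
  if (!all(dim(a) == geometry$grid_shape))
    stop_config("field grid %dx%d does not match geometry %dx%d",
                nrow(a), ncol(a), geometry$grid_shape[1], geometry$grid_shape[2])
  z <- geometry$distance
  if (z == 0) return(field)
  lambda <- optics$wavelength
  umax <- 1 / (2 * geometry$pixel_size)
  if (pi * lambda * z * umax^2 > pi)
    warning(sprintf(
      "Fresnel chirp aliases at Nyquist; maximum alias-safe distance is %.4g m",
      1 / (lambda * umax^2)), call. = FALSE)
  f2 <- freq_sq_grid(nrow(a), ncol(a), geometry$pixel_size)
  H <- exp(1i * optics$k * z) * exp(-1i * pi * lambda * z * f2)
  out <- stats::fft(stats::fft(a) * H, inverse = TRUE) / length(a)
  wave_field(out, field$pixel_size)
}

#' Intensity of a wave field
#'
#' @param field a [wave_field()].
#' @return real matrix of squared moduli.
#' @export
field_intensity <- function(field) {
  stopifnot(inherits(field, "wave_field"))
  Mod(field$amplitude)^2
}

#' Near-field intensity by the weak-object transport-of-intensity model
#'
#' Linearized edge-enhancement model: image contrast is proportional to the
#' Laplacian of the phase,
#' `I = I0 * (1 - (lambda z / 2 pi) * laplacian(phi))`,
#' with the Laplacian computed by a periodic 5-point stencil in physical
#' units. Negative values (the linearization can undershoot) are clipped at
#' zero; the clipped-pixel count is attached as attribute `"n_clipped"`.
#'
#' @param projection a `phantom_projection`.
#' @param geometry a [propagation_geometry()].
#' @param optics an [optical_constants()] object.
#' @return intensity matrix with attribute `n_clipped`.
#' @export
tie_intensity <- function(projection, geometry, optics) {
  stopifnot(inherits(projection, "phantom_projection"),
            inherits(geometry, "propagation_geometry"),
            inherits(optics, "optical_constants"))
  lap <- laplacian5(projection$phi, step = geometry$pixel_size)
  I <- projection$I0 *
    (1 - optics$wavelength * geometry$distance / (2 * pi) * lap)
  n_clip <- sum(I < 0)
  if (n_clip > 0) {
    I[I < 0] <- 0
    message(sprintf("tie_intensity: clipped %d negative pixel(s) at zero",
                    n_clip))
  }
  attr(I, "n_clipped") <- n_clip
  I
}
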