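# Detector model: PSF blur, Poisson shot noise, integer quantization.

#' Detector model
#'
#' @param psf_sigma Gaussian point-spread sd in pixels (0 disables blur);
#'   source-size and coherence blur are folded into this single PSF.
#' @param photons_per_pixel expected photon count at unit intensity.
#' @param bit_depth output integer depth (default 16).
#' @param seed integer seed for the shot noise (`NULL`: caller's RNG).
#' @param noise logical; `FALSE` records the expected counts exactly.
#' @return a `detector_model` object.
#' @export
detector_model <- function(psf_sigma = 1, photons_per_pixel = 1e5,
                           bit_depth = 16L, seed = NULL, noise = TRUE) {
  if (psf_sigma < 0) stop_config("`psf_sigma` must be >= 0")
  if (noise && (!is.numeric(photons_per_pixel) || photons_per_pixel <= 0))
    stop_config("`photons_per_pixel` must be > 0 when noise is enabled")
  structure(list(psf_sigma = psf_sigma,
                 photons_per_pixel = photons_per_pixel,
                 bit_depth = as.integer(bit_depth),
                 seed = seed, noise = isTRUE(noise)),
            class = "detector_model")
}

#' Record an intensity map with a detector
#'
#' Blurs with a normalized periodic Gaussian PSF, draws per-pixel Poisson
#' counts of mean `photons_per_pixel * intensity` (skipped when noise is
#' disabled), and min-max rescales the counts to the integer range of the
#' configured bit depth (a constant count field maps to full scale).
#'
#' @param intensity non-negative real matrix.
#' @param detector a [detector_model()].
#' @param pixel_size optional pixel pitch in meters, carried as metadata.
#' @return a `projection_image` with integer `pixels`, the raw `counts`,
#'   and acquisition metadata.
#' @export
detect <- function(intensity, detector = detector_model(),
                   pixel_size = NA_real_) {
  stopifnot(is.matrix(intensity), inherits(detector, "detector_model"))
  if (any(intensity < 0)) stop_config("`intensity` must be non-negative")
  blurred <- fft_gauss_blur(intensity, detector$psf_sigma)
  expected <- detector$photons_per_pixel * blurred
  counts <- if (detector$noise) {
    with_seed(detector$seed,
              matrix(stats::rpois(length(expected), expected),
                     nrow(expected), ncol(expected)))
  } else expected
  top <- 2^detector$bit_depth - 1
  rng <- range(counts)
  pixels <- if (rng[1] == rng[2]) {
    matrix(as.integer(top), nrow(counts), ncol(counts))
  } else {
    matrix(as.integer(round((counts - rng[1]) / (rng[2] - rng[1]) * top)),
           nrow(counts), ncol(counts))
  }
  projection_image(pixels, pixel_size = pixel_size,
                   meta = list(bit_depth = detector$bit_depth,
                               psf_sigma = detector$psf_sigma,
                               photons_per_pixel = detector$photons_per_pixel,
                               count_range = rng),
                   counts = counts)
}

#' Detector image container
#'
#' @param pixels integer matrix of detector values.
#' @param pixel_size pixel pitch in meters (may be `NA`).
#' @param meta named list of acquisition metadata.
#' @param counts optional raw photon-count matrix.
#' @return a `projection_image` object.
#' @export
projection_image <- function(pixels, pixel_size = NA_real_, meta = list(),
                             counts = NULL) {
  stopifnot(is.matrix(pixels))
  structure(list(pixels = pixels, pixel_size = pixel_size, meta = meta,
                 counts = counts),
            class = "projection_image")
}
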