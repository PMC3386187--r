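# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards. `seed = NULL` runs unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a master seed and context tokens
#'
#' Stage and image seeds are derived by folding the master seed with string
#' tokens (stage name, image index, ...) through a multiplicative hash, so
#' that adding images to a run never perturbs the seeds of earlier ones.
#' The result is always in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param ... character or numeric tokens identifying the child stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (tok in list(...)) {
    for (ch in utf8ToInt(paste0("/", as.character(tok)))) {
      h <- (h * 31 + ch) %% m
    }
  }
  as.integer(h %% (m - 1L) + 1L)
}

# FFT sample frequencies in cycles per sample (numpy fftfreq layout).
fft_freq <- function(n) {
  c(seq.int(0L, floor((n - 1) / 2)), seq.int(-ceiling((n - 1) / 2), -1L)) / n
}

# Squared spatial frequency grid |f|^2 in cycles^2 / m^2 for an nr x nc grid
# with the given pixel pitch in meters.
freq_sq_grid <- function(nr, nc, pixel_size) {
  fu <- fft_freq(nr) / pixel_size
  fv <- fft_freq(nc) / pixel_size
  outer(fu^2, fv^2, `+`)
}

# Periodic Gaussian blur via FFT with an exactly normalized kernel, matching
# the periodic boundary convention of the Fourier-optics propagator.
fft_gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  dr <- fft_freq(nr) * nr # signed sample offsets 0,1,...,-1
  dc <- fft_freq(nc) * nc
  kr <- exp(-dr^2 / (2 * sigma^2))
  kc <- exp(-dc^2 / (2 * sigma^2))
  ker <- outer(kr, kc)
  ker <- ker / sum(ker)
  Re(stats::fft(stats::fft(x) * stats::fft(ker), inverse = TRUE)) / length(x)
}

# Circular (periodic) 2-D Laplacian by the 5-point stencil, in 1/step^2 units.
laplacian5 <- function(x, step = 1) {
  nr <- nrow(x); nc <- ncol(x)
  up    <- x[c(2:nr, 1L), , drop = FALSE]
  down  <- x[c(nr, 1:(nr - 1L)), , drop = FALSE]
  left  <- x[, c(2:nc, 1L), drop = FALSE]
  right <- x[, c(nc, 1:(nc - 1L)), drop = FALSE]
  (up + down + left + right - 4 * x) / step^2
}

stop_config <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x) && x >= 1
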