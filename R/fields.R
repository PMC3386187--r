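# Internal texture-field primitives for the phantom generator.
# All use the caller's RNG stream (seeding is handled by build_liver_phantom).

# Stationary Gaussian random field with an approximately Gaussian
# autocorrelation of length `corr_len` pixels; zero mean, unit sd.
gauss_field <- function(nr, nc, corr_len) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_len <= 0) return(w)
  f2 <- freq_sq_grid(nr, nc, 1) # cycles^2 per px^2
  amp <- exp(-2 * pi^2 * corr_len^2 * f2)
  f <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / (nr * nc)
  f <- f - mean(f)
  s <- stats::sd(as.vector(f))
  if (s > 0) f / s else f
}

# Add a radially symmetric super-Gaussian bump exp(-(r/radius)^p) of peak
# `height` centered at (r0, c0); p = 6 gives the sharp, plateau-like profile
# used for necrotic lumps (edge-enhanceable boundary).
stamp_bump <- function(mat, r0, c0, radius, height, p = 6) {
  nr <- nrow(mat); nc <- ncol(mat)
  half <- ceiling(2 * radius)
  rr <- max(1L, floor(r0 - half)):min(nr, ceiling(r0 + half))
  cc <- max(1L, floor(c0 - half)):min(nc, ceiling(c0 + half))
  if (!length(rr) || !length(cc)) return(mat)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
  mat[rr, cc] <- mat[rr, cc] + height * exp(-(sqrt(d2) / radius)^p)
  mat
}

# Smooth curvilinear path: a momentum random walk starting at (r0, c0) with
# heading `theta0`; returns an n_steps x 2 matrix of (row, col) positions.
walk_path <- function(r0, c0, theta0, n_steps, wobble = 0.18, step = 1.5) {
  pos <- matrix(0, n_steps, 2)
  th <- theta0
  r <- r0; c <- c0
  for (i in seq_len(n_steps)) {
    pos[i, ] <- c(r, c)
    th <- th + stats::rnorm(1, 0, wobble)
    r <- r + step * sin(th)
    c <- c + step * cos(th)
  }
  pos
}

# Stamp a tube of Gaussian cross-section (sd `width` px, peak `height`)
# along a path given as (row, col) positions.
stamp_tube <- function(mat, path, width, height) {
  nr <- nrow(mat); nc <- ncol(mat)
  lay <- matrix(0, nr, nc)
  half <- ceiling(3 * width)
  for (i in seq_len(nrow(path))) {
    r0 <- path[i, 1]; c0 <- path[i, 2]
    if (r0 < 1 - half || r0 > nr + half || c0 < 1 - half || c0 > nc + half)
      next
    rr <- max(1L, floor(r0 - half)):min(nr, ceiling(r0 + half))
    cc <- max(1L, floor(c0 - half)):min(nc, ceiling(c0 + half))
    d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
    lay[rr, cc] <- pmax(lay[rr, cc], exp(-d2 / (2 * width^2)))
  }
  mat + height * lay
}
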