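# Independent reference implementations and small fixture builders used as
# oracles across the suite. These deliberately use naive loops and
# from-the-definition formulas, not the package's code paths.

# naive double-loop co-occurrence matrix
ref_glcm <- function(levels, Ng, offset, symmetric = TRUE) {
  C <- matrix(0, Ng, Ng)
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + offset[1]; c2 <- c + offset[2]
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
      i <- levels[r, c] + 1L; j <- levels[r2, c2] + 1L
      C[i, j] <- C[i, j] + 1
      if (symmetric) C[j, i] <- C[j, i] + 1
    }
  }
  C / sum(C)
}

# the nine features straight from their definitions
ref_features <- function(C) {
  Ng <- nrow(C)
  asm <- 0; inertia <- 0; idm <- 0; ent <- 0; cross <- 0
  px <- rowSums(C); py <- colSums(C)
  lev <- 0:(Ng - 1)
  mx <- sum(lev * px); my <- sum(lev * py)
  sx <- sqrt(sum((lev - mx)^2 * px)); sy <- sqrt(sum((lev - my)^2 * py))
  ps <- numeric(2 * Ng - 1); pd <- numeric(Ng)
  for (i in seq_len(Ng)) for (j in seq_len(Ng)) {
    v <- C[i, j]
    asm <- asm + v^2
    inertia <- inertia + (i - j)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    if (v > 0) ent <- ent - v * log(v)
    cross <- cross + (i - 1) * (j - 1) * v
    ps[i + j - 1] <- ps[i + j - 1] + v
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + v
  }
  corr <- if (sx * sy > 0) (cross - mx * my) / (sx * sy) else 0
  ent0 <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  c(asm = asm, inertia = inertia, idm = idm, entropy = ent,
    correlation = corr,
    sum_average = sum((0:(2 * Ng - 2)) * ps),
    difference_average = sum((0:(Ng - 1)) * pd),
    sum_entropy = ent0(ps), difference_entropy = ent0(pd))
}

random_quantized <- function(nr, nc, Ng) {
  structure(list(levels = matrix(sample.int(Ng, nr * nc, replace = TRUE) - 1L,
                                 nr, nc),
                 Ng = as.integer(Ng)),
            class = "quantized_patch")
}

# 4x4 binary checkerboard quantized patch (levels 0/1)
checkerboard_patch <- function(n = 4L) {
  cb <- (outer(seq_len(n), seq_len(n), `+`)) %% 2L
  structure(list(levels = matrix(as.integer(cb), n, n), Ng = 2L),
            class = "quantized_patch")
}

# eigenvalues of a symmetric 3x3 via its characteristic polynomial roots
ref_eigenvalues_3x3 <- function(A) {
  tr <- sum(diag(A))
  m <- function(i, j) A[i, i] * A[j, j] - A[i, j] * A[j, i]
  s2 <- m(1, 2) + m(1, 3) + m(2, 3)
  d <- det(A)
  # lambda^3 - tr lambda^2 + s2 lambda - d = 0
  r <- polyroot(c(-d, s2, -tr, 1))
  sort(Re(r), decreasing = TRUE)
}

# small centered Gaussian phase-bump projection for the optics tests
gauss_bump_projection <- function(n, phi0, sigma_px, pixel_size = 9e-6) {
  ctr <- n / 2
  r2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  structure(list(phi = phi0 * exp(-r2 / (2 * sigma_px^2)),
                 I0 = matrix(1, n, n), pixel_size = pixel_size),
            class = "phantom_projection")
}

# level-1 detail energy of a critically-sampled real separable wavelet
# (single tree: one fixed polyphase of the full-rate filter outputs)
dwt1_detail_energy <- function(x) {
  f <- dtcwt_filters()
  lo <- ilpcitex:::cconv_dim1(x, f$h0o)
  hi <- ilpcitex:::cconv_dim1(x, f$h1o)
  sub <- function(B) ilpcitex:::poly_split(B, 0L, 0L)
  sum(sub(ilpcitex:::cconv_dim2(lo, f$h1o))^2) +
    sum(sub(ilpcitex:::cconv_dim2(hi, f$h0o))^2) +
    sum(sub(ilpcitex:::cconv_dim2(hi, f$h1o))^2)
}
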