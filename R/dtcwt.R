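# Two-level dual-tree complex wavelet transform with perfect reconstruction.
#
# Implementation notes. Boundary handling is circular (periodic), so every
# tree is an exactly invertible filter bank: level 1 keeps the full-rate
# biorthogonal filter outputs and splits them into the four tree phases
# (reconstruction uses the zero-phase identity conv(h0,g0)+conv(h1,g1) =
# 2*delta); levels >= 2 apply the orthonormal Q-shift pair per tree, whose
# decimated circular analysis operator is orthogonal, so synthesis is its
# adjoint. The six oriented complex subbands per level are unitary
# combinations of the four tree subbands, hence invertible as well.

# zero-phase circular convolution along dim 1 (odd-length h)
cconv_dim1 <- function(X, h) {
  n <- nrow(X)
  ctr <- (length(h) + 1L) %/% 2L
  Y <- matrix(0, n, ncol(X))
  base <- seq_len(n) - 1L
  for (k in seq_along(h)) {
    idx <- ((base + k - ctr) %% n) + 1L
    Y <- Y + h[k] * X[idx, , drop = FALSE]
  }
  Y
}
cconv_dim2 <- function(X, h) t(cconv_dim1(t(X), h))

# decimate-by-2 circular analysis along dim 1 with an orthonormal pair
dec_dim1 <- function(X, h0, h1, origin = 7L) {
  n <- nrow(X); m <- n %/% 2L
  lo <- matrix(0, m, ncol(X)); hi <- lo
  base <- 2L * (seq_len(m) - 1L)
  for (k in seq_along(h0)) {
    idx <- ((base + k - origin) %% n) + 1L
    xs <- X[idx, , drop = FALSE]
    lo <- lo + h0[k] * xs
    hi <- hi + h1[k] * xs
  }
  list(lo = lo, hi = hi)
}

# adjoint (= inverse, orthonormal filters) of dec_dim1
adj_dim1 <- function(lo, hi, h0, h1, origin = 7L) {
  m <- nrow(lo); n <- 2L * m
  X <- matrix(0, n, ncol(lo))
  base <- 2L * (seq_len(m) - 1L)
  for (k in seq_along(h0)) {
    idx <- ((base + k - origin) %% n) + 1L
    X[idx, ] <- X[idx, , drop = FALSE] + h0[k] * lo + h1[k] * hi
  }
  X
}

poly_split <- function(X, pr, pc) {
  X[seq.int(1L + pr, nrow(X), 2L), seq.int(1L + pc, ncol(X), 2L),
    drop = FALSE]
}

poly_merge <- function(aa, ab, ba, bb) {
  n <- 2L * nrow(aa); m <- 2L * ncol(aa)
  X <- matrix(0, n, m)
  X[seq.int(1L, n, 2L), seq.int(1L, m, 2L)] <- aa
  X[seq.int(1L, n, 2L), seq.int(2L, m, 2L)] <- ab
  X[seq.int(2L, n, 2L), seq.int(1L, m, 2L)] <- ba
  X[seq.int(2L, n, 2L), seq.int(2L, m, 2L)] <- bb
  X
}

# unitary quad -> complex-pair combination and its exact inverse;
# a, b, c, d are the (row tree, col tree) = (A,A), (A,B), (B,A), (B,B)
# subbands of one 2-D band type.
quad_to_complex <- function(a, b, c, d) {
  s <- sqrt(0.5)
  list(z1 = s * ((a - d) + 1i * (c + b)),
       z2 = s * ((a + d) + 1i * (c - b)))
}
complex_to_quad <- function(z1, z2) {
  s <- sqrt(0.5)
  re1 <- Re(z1); im1 <- Im(z1); re2 <- Re(z2); im2 <- Im(z2)
  list(a = s * (re2 + re1), b = s * (im1 - im2),
       c = s * (im1 + im2), d = s * (re2 - re1))
}

reflect_pad <- function(X, pr, pc) {
  if (pr > 0) X <- rbind(X, X[nrow(X):(nrow(X) - pr + 1L), , drop = FALSE])
  if (pc > 0) X <- cbind(X, X[, ncol(X):(ncol(X) - pc + 1L), drop = FALSE])
  X
}

#' Forward dual-tree complex wavelet transform
#'
#' Decomposes a real patch into `levels` scales: six oriented complex
#' highpass subbands per level (quarter area per level) and the scaling
#' (lowpass) images. Odd or non-dyadic sizes are symmetric-reflection
#' padded to a multiple of `2^levels` (recorded and stripped on
#' inversion).
#'
#' @param x numeric matrix (patch); after padding each side must be at
#'   least `16 * 2^(levels - 1)` pixels for the deepest-level filters.
#' @param levels number of decomposition levels (default 2).
#' @return a `dtcwt_pyramid` with `highpass` (list of complex arrays,
#'   `dim = c(n/2^l, m/2^l, 6)`), `lowpass_levels` (tree-averaged real
#'   scaling image per level), and the per-tree lowpass images needed for
#'   exact inversion.
#' @export
dtcwt_forward <- function(x, levels = 2L) {
  stopifnot(is.matrix(x), is.numeric(x))
  levels <- as.integer(levels)
  if (levels < 1L) stop_config("`levels` must be >= 1")
  f <- dtcwt_filters()
  orig <- dim(x)
  blk <- 2L^levels
  pr <- (blk - orig[1] %% blk) %% blk
  pc <- (blk - orig[2] %% blk) %% blk
  if (pr > orig[1] || pc > orig[2])
    stop_config("patch %dx%d is too small for a %d-level transform",
                orig[1], orig[2], levels)
  x <- reflect_pad(x, pr, pc)
  if (min(dim(x)) < 16L * 2L^(levels - 1L))
    stop_config("patch %dx%d is too small for a %d-level transform",
                orig[1], orig[2], levels)

  highpass <- vector("list", levels)
  lowpass_levels <- vector("list", levels)

  # ---- level 1: full-rate biorthogonal filtering + tree-phase split ----
  lo1 <- cconv_dim1(x, f$h0o); hi1 <- cconv_dim1(x, f$h1o)
  LL <- cconv_dim2(lo1, f$h0o); LH <- cconv_dim2(lo1, f$h1o)
  HL <- cconv_dim2(hi1, f$h0o); HH <- cconv_dim2(hi1, f$h1o)
  bandc <- lapply(list(LH, HL, HH), function(B) {
    quad_to_complex(poly_split(B, 0L, 0L), poly_split(B, 0L, 1L),
                    poly_split(B, 1L, 0L), poly_split(B, 1L, 1L))
  })
  highpass[[1]] <- array(
    c(bandc[[1]]$z1, bandc[[1]]$z2, bandc[[2]]$z1, bandc[[2]]$z2,
      bandc[[3]]$z1, bandc[[3]]$z2),
    dim = c(nrow(LL) %/% 2L, ncol(LL) %/% 2L, 6L))
  # per-tree scaling images: (row tree, col tree) phases of full-rate LoLo
  Q <- list(aa = poly_split(LL, 0L, 0L), ab = poly_split(LL, 0L, 1L),
            ba = poly_split(LL, 1L, 0L), bb = poly_split(LL, 1L, 1L))
  lowpass_levels[[1]] <- (Q$aa + Q$ab + Q$ba + Q$bb) / 4

  # ---- levels >= 2: per-tree orthonormal Q-shift steps ----
  if (levels >= 2L) {
    for (l in 2:levels) {
      out <- list()
      for (rt in c("a", "b")) for (ct in c("a", "b")) {
        tr <- paste0(rt, ct)
        h0r <- f[[paste0("h0", rt)]]; h1r <- f[[paste0("h1", rt)]]
        h0c <- f[[paste0("h0", ct)]]; h1c <- f[[paste0("h1", ct)]]
        s1 <- dec_dim1(Q[[tr]], h0r, h1r)
        slo <- dec_dim1(t(s1$lo), h0c, h1c) # transposed: filters columns
        shi <- dec_dim1(t(s1$hi), h0c, h1c)
        out[[tr]] <- list(LL = t(slo$lo), LH = t(slo$hi),
                          HL = t(shi$lo), HH = t(shi$hi))
      }
      bandc <- lapply(c("LH", "HL", "HH"), function(b) {
        quad_to_complex(out$aa[[b]], out$ab[[b]], out$ba[[b]], out$bb[[b]])
      })
      highpass[[l]] <- array(
        c(bandc[[1]]$z1, bandc[[1]]$z2, bandc[[2]]$z1, bandc[[2]]$z2,
          bandc[[3]]$z1, bandc[[3]]$z2),
        dim = c(nrow(out$aa$LL), ncol(out$aa$LL), 6L))
      Q <- list(aa = out$aa$LL, ab = out$ab$LL,
                ba = out$ba$LL, bb = out$bb$LL)
      lowpass_levels[[l]] <- (Q$aa + Q$ab + Q$ba + Q$bb) / 4
    }
  }

  structure(list(levels = levels, orig_shape = orig, pad = c(pr, pc),
                 highpass = highpass, lowpass_quads = Q,
                 lowpass_levels = lowpass_levels),
            class = "dtcwt_pyramid")
}

#' Inverse dual-tree complex wavelet transform
#'
#' Exactly reconstructs the patch from a [dtcwt_forward()] pyramid
#' (machine-precision perfect reconstruction) and strips any recorded
#' padding.
#'
#' @param pyramid a `dtcwt_pyramid`.
#' @return the reconstructed real matrix.
#' @export
dtcwt_inverse <- function(pyramid) {
  stopifnot(inherits(pyramid, "dtcwt_pyramid"))
  f <- dtcwt_filters()
  Q <- pyramid$lowpass_quads
  levels <- pyramid$levels
  if (levels >= 2L) {
    for (l in levels:2) {
      hp <- pyramid$highpass[[l]]
      if (!all(dim(hp)[1:2] == dim(Q$aa)))
        stop_config("pyramid level %d shapes are inconsistent", l)
      qd <- lapply(1:3, function(b) {
        complex_to_quad(hp[, , 2 * b - 1L], hp[, , 2 * b])
      })
      newQ <- list()
      for (tr in c("aa", "ab", "ba", "bb")) {
        rt <- substr(tr, 1, 1); ct <- substr(tr, 2, 2)
        key <- c(aa = "a", ab = "b", ba = "c", bb = "d")[[tr]]
        h0r <- f[[paste0("h0", rt)]]; h1r <- f[[paste0("h1", rt)]]
        h0c <- f[[paste0("h0", ct)]]; h1c <- f[[paste0("h1", ct)]]
        LH <- qd[[1]][[key]]; HL <- qd[[2]][[key]]; HH <- qd[[3]][[key]]
        tlo <- t(adj_dim1(t(Q[[tr]]), t(LH), h0c, h1c))
        thi <- t(adj_dim1(t(HL), t(HH), h0c, h1c))
        newQ[[tr]] <- adj_dim1(tlo, thi, h0r, h1r)
      }
      Q <- newQ
    }
  }
  # ---- level 1 inverse ----
  hp <- pyramid$highpass[[1]]
  if (!all(dim(hp)[1:2] == dim(Q$aa)))
    stop_config("pyramid level 1 shapes are inconsistent")
  LL <- poly_merge(Q$aa, Q$ab, Q$ba, Q$bb)
  qd <- lapply(1:3, function(b) complex_to_quad(hp[, , 2 * b - 1L], hp[, , 2 * b]))
  mk <- function(q) poly_merge(Re(q$a), Re(q$b), Re(q$c), Re(q$d))
  LH <- mk(qd[[1]]); HL <- mk(qd[[2]]); HH <- mk(qd[[3]])
  lo1 <- cconv_dim2(LL, f$g0o) + cconv_dim2(LH, f$g1o)
  hi1 <- cconv_dim2(HL, f$g0o) + cconv_dim2(HH, f$g1o)
  x <- (cconv_dim1(lo1, f$g0o) + cconv_dim1(hi1, f$g1o)) / 4
  x[seq_len(pyramid$orig_shape[1]), seq_len(pyramid$orig_shape[2]),
    drop = FALSE]
}

#' The four subband images of a two-level decomposition
#'
#' `LF1`, `LF2` are the tree-averaged real scaling images at levels 1 and
#' 2; `HF1`, `HF2` are the root-mean-square aggregates of the six oriented
#' complex subband magnitudes at each level (non-negative by construction).
#'
#' @param pyramid a two-level (or deeper) `dtcwt_pyramid`.
#' @return list with elements `HF1`, `HF2`, `LF1`, `LF2`.
#' @export
subband_images <- function(pyramid) {
  stopifnot(inherits(pyramid, "dtcwt_pyramid"))
  if (pyramid$levels < 2L)
    stop_config("a 2-level pyramid is required, got %d level(s)",
                pyramid$levels)
  rms6 <- function(hp) {
    m2 <- Mod(hp)^2
    sqrt(apply(m2, c(1, 2), mean))
  }
  list(HF1 = rms6(pyramid$highpass[[1]]),
       HF2 = rms6(pyramid$highpass[[2]]),
       LF1 = pyramid$lowpass_levels[[1]],
       LF2 = pyramid$lowpass_levels[[2]])
}

#' Texture features of the four wavelet subband images
#'
#' Quantizes each of `HF1`, `HF2`, `LF1`, `LF2` (per-image min-max, `Ng`
#' levels) and computes the orientation-averaged nine co-occurrence
#' features.
#'
#' @param sub a [subband_images()] list.
#' @param Ng gray levels (default 16).
#' @param distance co-occurrence distance in pixels.
#' @return named list of four nine-feature vectors.
#' @export
subband_texture <- function(sub, Ng = 16L, distance = 1L) {
  stopifnot(all(c("HF1", "HF2", "LF1", "LF2") %in% names(sub)))
  lapply(sub[c("HF1", "HF2", "LF1", "LF2")], function(img) {
    if (min(dim(img)) < 8L)
      stop_config("subband image %dx%d is smaller than 8x8",
                  nrow(img), ncol(img))
    orientation_average(quantize(img, Ng), distance)
  })
}

#' Subband texture table for a list of ROI patches
#'
#' Runs the two-level transform on each patch and extracts the four
#' subband texture vectors.
#'
#' @param rois list of `roi_patch` objects.
#' @param Ng gray levels.
#' @param levels decomposition levels (default 2).
#' @param distance co-occurrence distance.
#' @return data.frame with columns `source_id`, `region_label`, `stage`,
#'   `subband` and the nine features.
#' @export
subband_texture_features <- function(rois, Ng = 16L, levels = 2L,
                                     distance = 1L) {
  rows <- lapply(rois, function(p) {
    sub <- subband_images(dtcwt_forward(p$pixels, levels))
    vs <- subband_texture(sub, Ng, distance)
    do.call(rbind, lapply(names(vs), function(nm) {
      cbind(data.frame(source_id = p$source_id,
                       region_label = p$region_label,
                       stage = p$stage, subband = nm,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(vs[[nm]])))
    }))
  })
  do.call(rbind, rows)
}
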