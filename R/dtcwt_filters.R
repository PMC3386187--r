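# Filter bank of the dual-tree complex wavelet transform.
#
# Level 1 uses the CDF 9/7 biorthogonal pair (odd-length, linear phase);
# the two trees are the even/odd sample phases of the full-rate filter
# outputs, i.e. the standard one-sample-offset level-1 construction.
# Levels >= 2 use a 14-tap orthonormal Q-shift lowpass with group delay
# ~(L-1)/2 - 1/4; tree B is its time reverse, so the two trees differ by
# half a (downsampled) sample period as the dual tree requires.
# The Q-shift coefficients satisfy the orthonormality conditions
# sum_n h[n] h[n+2k] = delta_k and sum h = sqrt(2) to < 2e-16.

DTCWT_H0O <- c( 0.03782845550726404, -0.02384946501955684,
               -0.11062440441843718,  0.37740285561283066,
                0.85269867900889380,  0.37740285561283066,
               -0.11062440441843718, -0.02384946501955684,
                0.03782845550726404)

DTCWT_H1O <- c(-0.06453888262869706,  0.04068941760916406,
                0.41809227322161724, -0.78848561640558290,
                0.41809227322161724,  0.04068941760916406,
               -0.06453888262869706)

DTCWT_G0O <- c(-0.06453888262869706, -0.04068941760916406,
                0.41809227322161724,  0.78848561640558290,
                0.41809227322161724, -0.04068941760916406,
               -0.06453888262869706)

DTCWT_G1O <- c(-0.03782845550726404, -0.02384946501955684,
                0.11062440441843718,  0.37740285561283066,
               -0.85269867900889380,  0.37740285561283066,
                0.11062440441843718, -0.02384946501955684,
               -0.03782845550726404)

DTCWT_H0A <- c( 0.00331493060074956, -0.00395392336563292,
                0.03470830125211228, -0.03894202049358896,
               -0.11729765259772580,  0.27538245799413119,
                0.75607137434189997,  0.56882730965335726,
                0.01195399546627328, -0.10674443194010606,
                0.02383064485740422,  0.01712741868078538,
               -0.00547481273416597, -0.00459002934239838)

# Conjugate-quadrature highpass of an even-length orthonormal lowpass:
# h1[k] = (-1)^(k-1) h0[L-k+1] (1-based alternating flip).
cqf_highpass <- function(h0) {
  L <- length(h0)
  rev(h0) * (-1)^(seq_len(L) - 1)
}

#' Filters of the dual-tree complex wavelet transform
#'
#' @return named list: level-1 biorthogonal analysis/synthesis pairs
#'   (`h0o`, `h1o`, `g0o`, `g1o`, CDF 9/7) and the level-2+ orthonormal
#'   Q-shift pairs of the two trees (`h0a`, `h1a`, `h0b`, `h1b`, 14 taps,
#'   tree B time-reversed from tree A).
#' @export
dtcwt_filters <- function() {
  h0a <- DTCWT_H0A
  h0b <- rev(h0a)
  list(h0o = DTCWT_H0O, h1o = DTCWT_H1O, g0o = DTCWT_G0O, g1o = DTCWT_G1O,
       h0a = h0a, h1a = cqf_highpass(h0a),
       h0b = h0b, h1b = cqf_highpass(h0b))
}
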