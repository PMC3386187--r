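# Gray-level co-occurrence matrices and the nine Haralick texture
# parameters: angular second moment, inertia, inverse difference moment,
# entropy, correlation, sum average, difference average, sum entropy and
# difference entropy. Entropies use the natural logarithm (the log base
# only rescales a feature and is absorbed by standardization in the PCA).

#' Compute a gray-level co-occurrence matrix
#'
#' Counts all in-bounds ordered level pairs `(p, p + offset)` in the
#' quantized patch; with `symmetric = TRUE` the transposed counts are added
#' before normalizing to a joint probability matrix `C` with
#' `sum(C) == 1`.
#'
#' @param q a [quantize()]d patch.
#' @param offset integer `c(drow, dcol)` displacement in pixels (nonzero).
#' @param symmetric logical; symmetrize the pair counts (default `TRUE`).
#' @return a `glcm` object with fields `C` (`Ng x Ng`), `offset`,
#'   `symmetric`, `Ng`.
#' @export
compute_glcm <- function(q, offset = c(0L, 1L), symmetric = TRUE) {
  stopifnot(inherits(q, "quantized_patch"))
  offset <- as.integer(offset)
  if (length(offset) != 2L || all(offset == 0L))
    stop_config("`offset` must be a nonzero integer pair")
  lv <- q$levels; Ng <- q$Ng
  nr <- nrow(lv); nc <- ncol(lv)
  dr <- offset[1]; dc <- offset[2]
  rs <- seq_len(nr); cs <- seq_len(nc)
  r1 <- rs[rs + dr >= 1L & rs + dr <= nr]
  c1 <- cs[cs + dc >= 1L & cs + dc <= nc]
  if (!length(r1) || !length(c1))
    stop_config("patch %dx%d has no pixel pairs at offset (%d, %d)",
                nr, nc, dr, dc)
  i <- lv[r1, c1, drop = FALSE]
  j <- lv[r1 + dr, c1 + dc, drop = FALSE]
  counts <- matrix(tabulate(i * Ng + j + 1L, nbins = Ng * Ng),
                   Ng, Ng, byrow = TRUE) # row = i, col = j
  if (symmetric) counts <- counts + t(counts)
  structure(list(C = counts / sum(counts), offset = offset,
                 symmetric = isTRUE(symmetric), Ng = Ng),
            class = "glcm")
}

#' Marginal statistics of a co-occurrence matrix
#'
#' Row/column marginals `px`, `py` with their means and standard deviations
#' on the 0-based level indices, plus the sum distribution `p_sum(k)` over
#' `k = i + j` in `0..2(Ng-1)` and the absolute-difference distribution
#' `p_diff(k)` over `k = |i - j|` in `0..Ng-1`.
#'
#' @param glcm a [compute_glcm()] result.
#' @return a `marginal_stats` list.
#' @export
marginal_stats <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  C <- glcm$C; Ng <- glcm$Ng
  lev <- 0:(Ng - 1)
  px <- rowSums(C); py <- colSums(C)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px))
  sd_y <- sqrt(sum((lev - mu_y)^2 * py))
  ii <- matrix(lev, Ng, Ng); jj <- t(ii)
  p_sum <- as.vector(tapply(C, ii + jj, sum))
  p_sum_full <- numeric(2 * Ng - 1)
  p_sum_full[sort(unique(as.vector(ii + jj))) + 1] <- p_sum
  p_diff <- as.vector(tapply(C, abs(ii - jj), sum))
  p_diff_full <- numeric(Ng)
  p_diff_full[sort(unique(as.vector(abs(ii - jj)))) + 1] <- p_diff
  structure(list(px = px, py = py, mu_x = mu_x, mu_y = mu_y,
                 sd_x = sd_x, sd_y = sd_y,
                 p_sum = p_sum_full, p_diff = p_diff_full),
            class = "marginal_stats")
}

entropy0 <- function(p) { # -sum p log p with 0 log 0 := 0
  p <- p[p > 0]
  -sum(p * log(p))
}

#' The nine co-occurrence texture parameters
#'
#' Computes, from one GLCM: angular second moment `sum(C^2)`; inertia
#' `sum((i-j)^2 C)`; inverse difference moment `sum(C / (1 + (i-j)^2))`;
#' entropy `-sum(C log C)`; correlation
#' `(sum(i j C) - mu_x mu_y) / (sd_x sd_y)` (defined as 0 when a marginal
#' is degenerate); sum average `sum(k p_sum(k))`; difference average
#' `sum(k p_diff(k))`; sum entropy and difference entropy.
#'
#' @param glcm a [compute_glcm()] result.
#' @return named numeric vector of the nine features.
#' @export
texture_vector <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  C <- glcm$C; Ng <- glcm$Ng
  lev <- 0:(Ng - 1)
  ii <- matrix(lev, Ng, Ng); jj <- t(ii)
  m <- marginal_stats(glcm)
  corr <- if (m$sd_x * m$sd_y > 0) {
    (sum(ii * jj * C) - m$mu_x * m$mu_y) / (m$sd_x * m$sd_y)
  } else 0
  ks <- 0:(2 * Ng - 2); kd <- 0:(Ng - 1)
  c(asm = sum(C^2),
    inertia = sum((ii - jj)^2 * C),
    idm = sum(C / (1 + (ii - jj)^2)),
    entropy = entropy0(C),
    correlation = corr,
    sum_average = sum(ks * m$p_sum),
    difference_average = sum(kd * m$p_diff),
    sum_entropy = entropy0(m$p_sum),
    difference_entropy = entropy0(m$p_diff))
}

glcm_feature_names <- function() {
  c("asm", "inertia", "idm", "entropy", "correlation",
    "sum_average", "difference_average", "sum_entropy", "difference_entropy")
}

#' Orientation-averaged texture vector of a quantized patch
#'
#' Mean of [texture_vector()] over the four symmetric co-occurrence
#' offsets at the given distance: 0, 45, 90 and 135 degrees, i.e.
#' `(0, d)`, `(-d, d)`, `(-d, 0)`, `(-d, -d)`.
#'
#' @param q a [quantize()]d patch.
#' @param distance offset distance in pixels (default 1).
#' @return named numeric vector of the nine orientation-averaged features.
#' @export
orientation_average <- function(q, distance = 1L) {
  d <- as.integer(distance)
  offs <- list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d))
  vecs <- vapply(offs,
                 function(o) texture_vector(compute_glcm(q, o, symmetric = TRUE)),
                 numeric(9L))
  rowMeans(vecs)
}

#' Texture feature table for a list of ROI patches
#'
#' Quantizes each patch and computes the orientation-averaged nine-feature
#' vector, returning one row per ROI with its labels.
#'
#' @param rois list of `roi_patch` objects from [sample_rois()].
#' @param Ng gray levels for [quantize()].
#' @param distance co-occurrence distance in pixels.
#' @return data.frame with columns `source_id`, `region_label`, `stage`
#'   and the nine features.
#' @export
texture_features <- function(rois, Ng = 16L, distance = 1L) {
  rows <- lapply(rois, function(p) {
    v <- orientation_average(quantize(p, Ng), distance)
    cbind(data.frame(source_id = p$source_id, region_label = p$region_label,
                     stage = p$stage, stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  do.call(rbind, rows)
}
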