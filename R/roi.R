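# ROI sampling inside labeled regions and gray-level quantization.

region_codes <- function() c(background = 0L, normal = 1L, tumor = 2L)

#' Sample square regions of interest inside a labeled region
#'
#' Draws `n` patches of `size x size` pixels whose footprint lies entirely
#' inside the pixels carrying `region_label` in `mask`. Placement is uniform
#' over all admissible origins; with `disjoint = TRUE` patches are pairwise
#' non-overlapping (rejection sampling with a bounded retry budget).
#'
#' @param image a `projection_image` or numeric matrix.
#' @param mask integer label matrix of the same shape (0 background,
#'   1 normal, 2 tumor).
#' @param region_label `"normal"` or `"tumor"`.
#' @param n number of patches (default 20, the per-region ROI count).
#' @param size patch side in pixels (default 60).
#' @param seed integer seed (`NULL`: caller's RNG).
#' @param disjoint logical; require pairwise non-overlapping patches.
#' @param stage optional stage label carried on each patch.
#' @param source_id optional source-image identifier.
#' @return list of `roi_patch` objects with fields `pixels`, `origin`
#'   (0-based `c(row, col)`), `region_label`, `stage`, `source_id`.
#' @export
sample_rois <- function(image, mask, region_label = c("tumor", "normal"),
                        n = 20L, size = 60L, seed = NULL, disjoint = FALSE,
                        stage = NA_character_, source_id = NA_character_) {
  region_label <- match.arg(region_label)
  pix <- if (inherits(image, "projection_image")) image$pixels else image
  stopifnot(is.matrix(pix), is.matrix(mask))
  if (!all(dim(pix) == dim(mask)))
    stop_config("`mask` shape %dx%d does not match image %dx%d",
                nrow(mask), ncol(mask), nrow(pix), ncol(pix))
  if (!is_count(n)) stop_config("`n` must be a positive integer")
  if (!is_count(size) || size < 2) stop_config("`size` must be an integer >= 2")
  nr <- nrow(pix); nc <- ncol(pix)
  if (size > nr || size > nc)
    stop_config("patch size %d exceeds the %dx%d image", size, nr, nc)

  code <- region_codes()[[region_label]]
  inside <- matrix(as.numeric(mask == code), nr, nc)
  # zero-padded summed-area table -> region-pixel count under every window
  sat <- rbind(0, cbind(0, t(apply(apply(inside, 2L, cumsum), 1L, cumsum))))
  orr <- seq_len(nr - size + 1L); orc <- seq_len(nc - size + 1L)
  full <- sat[orr + size, orc + size, drop = FALSE] -
    sat[orr, orc + size, drop = FALSE] -
    sat[orr + size, orc, drop = FALSE] +
    sat[orr, orc, drop = FALSE]
  admissible <- which(abs(full - size^2) < 0.5) # linear indices, origin grid
  if (!length(admissible))
    stop_config("region '%s' admits no %dx%d patch (capacity 0)",
                region_label, size, size)

  norig <- nr - size + 1L
  pick_origin <- function(i) {
    c((i - 1L) %% norig + 1L, (i - 1L) %/% norig + 1L)
  }
  with_seed(seed, {
    origins <- vector("list", n)
    if (!disjoint) {
      draw <- admissible[sample.int(length(admissible), n, replace = TRUE)]
      for (i in seq_len(n)) origins[[i]] <- pick_origin(draw[i])
    } else {
      placed <- 0L; tries <- 0L
      while (placed < n) {
        if (tries >= 10000L)
          stop_config(
            "could not place %d disjoint %dx%d patches in region '%s'; maximum feasible n here is %d",
            n, size, size, region_label, placed)
        tries <- tries + 1L
        cand <- pick_origin(admissible[sample.int(length(admissible), 1L)])
        ok <- TRUE
        for (j in seq_len(placed)) {
          o <- origins[[j]]
          if (abs(o[1] - cand[1]) < size && abs(o[2] - cand[2]) < size) {
            ok <- FALSE; break
          }
        }
        if (ok) {
          placed <- placed + 1L
          origins[[placed]] <- cand
        }
      }
    }
    lapply(origins, function(o) {
      structure(
        list(pixels = pix[o[1]:(o[1] + size - 1L),
                          o[2]:(o[2] + size - 1L), drop = FALSE],
             origin = c(row = o[1] - 1L, col = o[2] - 1L), # 0-based
             region_label = region_label, stage = stage,
             source_id = source_id),
        class = "roi_patch")
    })
  })
}

#' Quantize a patch to Ng gray levels
#'
#' Affine min-max mapping to `{0, ..., Ng - 1}`:
#' `level = floor((v - min) / (max - min) * Ng)` with the maximum mapped to
#' `Ng - 1`. Constant patches map to all zeros. The mapping is monotone, so
#' per-patch quantization makes the downstream co-occurrence features
#' invariant to affine illumination changes.
#'
#' @param patch an `roi_patch` or numeric matrix.
#' @param Ng number of gray levels (>= 2; default 16).
#' @return a `quantized_patch` with integer `levels` and `Ng`.
#' @export
quantize <- function(patch, Ng = 16L) {
  if (!is_count(Ng) || Ng < 2) stop_config("`Ng` must be an integer >= 2")
  v <- if (inherits(patch, "roi_patch")) patch$pixels else patch
  stopifnot(is.matrix(v))
  lo <- min(v); hi <- max(v)
  lv <- if (hi == lo) {
    matrix(0L, nrow(v), ncol(v))
  } else {
    l <- floor((v - lo) / (hi - lo) * Ng)
    l[l >= Ng] <- Ng - 1
    matrix(as.integer(l), nrow(v), ncol(v))
  }
  structure(list(levels = lv, Ng = as.integer(Ng)), class = "quantized_patch")
}
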