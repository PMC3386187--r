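# Co-occurrence matrices and the nine texture parameters.

test_that("GLCM of degenerate and hand-checked patches is exact", {
  # constant patch: single entry C_gg = 1
  qc <- structure(list(levels = matrix(3L, 4, 4), Ng = 16L),
                  class = "quantized_patch")
  g <- compute_glcm(qc, c(0L, 1L))
  expect_equal(g$C[4, 4], 1)
  expect_equal(sum(g$C), 1)

  # binary checkerboard at offset (0,1): C_01 = C_10 = 0.5
  g2 <- compute_glcm(checkerboard_patch(), c(0L, 1L), symmetric = TRUE)
  expect_equal(g2$C, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  expect_error(compute_glcm(qc, c(0L, 0L)), "nonzero")
  expect_error(compute_glcm(qc, c(0L, 10L)), "no pixel pairs")
})

test_that("GLCM equals the brute-force pair-enumeration oracle", {
  set.seed(7)
  for (rep in 1:25) {
    Ng <- sample(2:8, 1)
    q <- random_quantized(sample(4:10, 1), sample(4:10, 1), Ng)
    off <- c(sample(-2:2, 1), sample(-2:2, 1))
    if (all(off == 0)) off <- c(0L, 1L)
    for (sym in c(TRUE, FALSE)) {
      got <- compute_glcm(q, off, symmetric = sym)
      expect_equal(got$C, ref_glcm(q$levels, Ng, off, sym), tolerance = 1e-14)
    }
  }
})

test_that("marginal statistics follow their definitions", {
  g <- compute_glcm(checkerboard_patch(), c(0L, 1L))
  m <- marginal_stats(g)
  expect_equal(m$mu_x, 0.5); expect_equal(m$mu_y, 0.5)
  expect_equal(m$sd_x^2, 0.25); expect_equal(m$sd_y^2, 0.25)
  expect_equal(sum(m$p_sum), 1, tolerance = 1e-12)
  expect_equal(sum(m$p_diff), 1, tolerance = 1e-12)

  # constant patch: point-mass marginal, zero sd
  qc <- structure(list(levels = matrix(2L, 5, 5), Ng = 4L),
                  class = "quantized_patch")
  mc <- marginal_stats(compute_glcm(qc, c(0L, 1L)))
  expect_equal(mc$px, c(0, 0, 1, 0))
  expect_equal(mc$sd_x, 0)

  # symmetric GLCM: identical marginals
  set.seed(11)
  gs <- compute_glcm(random_quantized(8, 8, 5), c(1L, 1L), symmetric = TRUE)
  ms <- marginal_stats(gs)
  expect_identical(ms$px, ms$py)
  expect_identical(ms$mu_x, ms$mu_y)
  expect_identical(ms$sd_x, ms$sd_y)
})

test_that("the nine texture parameters match hand computations", {
  # constant patch at level g: asm 1, inertia 0, idm 1, entropy 0,
  # degenerate correlation 0, sum average 2g, difference average 0
  qc <- structure(list(levels = matrix(3L, 4, 4), Ng = 16L),
                  class = "quantized_patch")
  tv <- texture_vector(compute_glcm(qc, c(0L, 1L)))
  expect_equal(tv[["asm"]], 1)
  expect_equal(tv[["inertia"]], 0)
  expect_equal(tv[["idm"]], 1)
  expect_equal(tv[["entropy"]], 0)
  expect_equal(tv[["correlation"]], 0)
  expect_equal(tv[["sum_average"]], 6)
  expect_equal(tv[["difference_average"]], 0)

  # checkerboard at offset (0,1)
  tb <- texture_vector(compute_glcm(checkerboard_patch(), c(0L, 1L)))
  expect_equal(tb[["asm"]], 0.5)
  expect_equal(tb[["inertia"]], 1)
  expect_equal(tb[["idm"]], 0.5)
  expect_equal(tb[["entropy"]], log(2))
  expect_equal(tb[["correlation"]], -1)
  expect_equal(tb[["sum_average"]], 1)
  expect_equal(tb[["difference_average"]], 1)
  expect_equal(tb[["sum_entropy"]], 0)
  expect_equal(tb[["difference_entropy"]], 0)
})

test_that("all nine features equal the independent oracle on random GLCMs", {
  set.seed(13)
  for (rep in 1:200) {
    Ng <- sample(2:10, 1)
    q <- random_quantized(sample(5:12, 1), sample(5:12, 1), Ng)
    off <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
                c(0L, 2L))[[sample(5, 1)]]
    g <- compute_glcm(q, off, symmetric = TRUE)
    expect_equal(texture_vector(g), ref_features(g$C), tolerance = 1e-12)
  }
})

test_that("constant-image asm is the maximum, uniform spread the entropy max", {
  set.seed(17)
  asms <- numeric(50); ents <- numeric(50)
  for (rep in 1:50) {
    g <- compute_glcm(random_quantized(8, 8, 4), c(0L, 1L))
    tv <- texture_vector(g)
    asms[rep] <- tv[["asm"]]; ents[rep] <- tv[["entropy"]]
  }
  qc <- structure(list(levels = matrix(0L, 8, 8), Ng = 4L),
                  class = "quantized_patch")
  const <- texture_vector(compute_glcm(qc, c(0L, 1L)))
  expect_true(all(asms < const[["asm"]]))  # asm maximal for a point mass
  expect_true(all(ents > const[["entropy"]])) # entropy minimal there
})

test_that("orientation averaging is the mean over the four offsets", {
  # constant patch: all orientations identical
  qc <- structure(list(levels = matrix(5L, 8, 8), Ng = 16L),
                  class = "quantized_patch")
  oa <- orientation_average(qc)
  expect_equal(oa, texture_vector(compute_glcm(qc, c(0L, 1L))))

  # equals the arithmetic mean of the per-offset vectors
  set.seed(19)
  q <- random_quantized(9, 9, 6)
  offs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  man <- rowMeans(vapply(offs, function(o)
    texture_vector(compute_glcm(q, o)), numeric(9)))
  expect_equal(orientation_average(q), man, tolerance = 1e-14)

  # checkerboard: 0-degree inertia 1, 45-degree inertia 0 -> average 0.5
  cb <- checkerboard_patch(6L)
  expect_equal(texture_vector(compute_glcm(cb, c(0L, 1L)))[["inertia"]], 1)
  expect_equal(texture_vector(compute_glcm(cb, c(-1L, 1L)))[["inertia"]], 0)
  expect_equal(orientation_average(cb)[["inertia"]], 0.5)
})
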