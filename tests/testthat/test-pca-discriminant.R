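# Correlation PCA, contribution-rate selection, sign discriminant and
# stage monotonicity.

test_that("standardization yields unit columns and handles degeneracy", {
  set.seed(1)
  x <- matrix(rnorm(200), 40, 5)
  colnames(x) <- paste0("f", 1:5)
  std <- standardize_features(x)
  expect_true(all(abs(colMeans(std$x)) < 1e-12))
  expect_equal(unname(apply(std$x, 2, sd)), rep(1, 5), tolerance = 1e-12)
  # stored parameters reproduce the standardized matrix
  again <- sweep(sweep(x, 2, std$center), 2, std$scale, `/`)
  expect_equal(again, std$x)

  xc <- cbind(x, constant = 1)
  expect_warning(sc <- standardize_features(xc), "constant")
  expect_identical(sc$dropped, "constant")
  expect_identical(ncol(sc$x), 5L)
  expect_error(standardize_features(matrix(1, 10, 3)), "constant")
  expect_error(standardize_features(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("correlation PCA has the contribution-rate identities", {
  set.seed(2)
  # duplicated feature: rank-1 correlation, CR1 = 100%
  v <- rnorm(30)
  m <- pca_fit(standardize_features(cbind(a = v, b = v)))
  expect_equal(m$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(m$cr[1], 1, tolerance = 1e-12)

  # independent columns: every CR near 1/9
  x <- matrix(rnorm(10000 * 9), 10000, 9)
  m9 <- pca_fit(standardize_features(x))
  expect_true(all(abs(m9$cr - 1 / 9) < 0.02))

  # sum of CRs is 1; eigenvectors orthonormal
  y <- matrix(rnorm(50 * 6), 50, 6)
  mf <- pca_fit(standardize_features(y))
  expect_equal(sum(mf$cr), 1, tolerance = 1e-12)
  expect_equal(crossprod(mf$vectors), diag(6), tolerance = 1e-10)
})

test_that("eigendecomposition matches a characteristic-polynomial oracle", {
  set.seed(3)
  for (rep in 1:20) {
    x <- matrix(rnorm(40 * 3), 40, 3)
    R <- cor(x)
    expect_equal(pca_fit(standardize_features(x))$eigenvalues,
                 ref_eigenvalues_3x3(R), tolerance = 1e-8)
  }
})

test_that("scores have eigenvalue variances and are uncorrelated", {
  set.seed(4)
  x <- matrix(rnorm(80 * 5), 80, 5) + rnorm(80) # shared factor -> correlated
  std <- standardize_features(x)
  m <- pca_fit(std)
  sc <- pca_scores(m, std)
  expect_equal(unname(apply(sc, 2, var)), m$eigenvalues, tolerance = 1e-8)
  cv <- cov(sc)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  # duplicated rows give identical scores
  x2 <- rbind(x, x[1, ])
  std2 <- standardize_features(x2)
  sc2 <- pca_scores(pca_fit(std2), std2)
  expect_equal(sc2[81, ], sc2[1, ])
  expect_error(pca_scores(m, std$x[, 1:3]), "columns")
})

test_that("sign orientation makes the reference-group mean non-negative", {
  set.seed(5)
  x <- rbind(matrix(rnorm(40, mean = 2), 20, 2),
             matrix(rnorm(40, mean = -2), 20, 2))
  labels <- rep(c("normal", "tumor"), each = 20)
  std <- standardize_features(x)
  m <- pca_fit(std)
  m$vectors[, 1] <- -abs(m$vectors[, 1]) # force a negative orientation
  mo <- orient_signs(m, std, labels)
  sc <- pca_scores(mo, std)
  expect_gte(mean(sc[labels == "normal", 1]), 0)
  # orientation never changes magnitudes or eigenvalues
  expect_equal(abs(pca_scores(m, std)), abs(sc))
  expect_identical(mo$eigenvalues, m$eigenvalues)
  # already-positive reference: identity
  m2 <- orient_signs(mo, std, labels)
  expect_identical(m2$flips, mo$flips)
  expect_error(orient_signs(m, std, labels, reference_label = "none"),
               "absent")
  # unsupervised fallback: largest-magnitude loading positive
  mu <- orient_signs(m, std, labels = NULL)
  v1 <- mu$vectors[, 1] * mu$flips[1]
  expect_gt(v1[which.max(abs(v1))], 0)
})

test_that("component selection implements the cumulative CR rule", {
  fake <- function(cr) structure(list(cr = cr), class = "pca_model")
  expect_identical(select_components(fake(c(0.9157, 0.05, 0.0343))), 1L)
  expect_identical(select_components(fake(c(0.5, 0.4, 0.1))), c(1L, 2L))
  expect_identical(select_components(fake(c(0.5, 0.4, 0.1)), 1.0), 1:3)
})

test_that("the F1 sign rule discriminates and ties go to normal", {
  sc <- cbind(F1 = c(1.4, 0.9, -1.6, -2.0))
  rep <- sign_discriminate(sc, c("normal", "normal", "tumor", "tumor"),
                           cr1 = 0.9)
  expect_equal(rep$agreement, 1)
  expect_equal(rep$group_stats$normal[["mean"]], 1.15)
  sc0 <- cbind(F1 = c(0, -1))
  rep0 <- sign_discriminate(sc0, c("normal", "tumor"))
  expect_identical(rep0$predicted[1], "normal")
})

test_that("stage monotonicity is the Spearman rank statistic", {
  expect_equal(stage_monotonicity(c(1, 2, 3, 4))$rho, 1)
  expect_equal(stage_monotonicity(c(4, 3, 2, 1))$rho, -1)
  m <- stage_monotonicity(c(1, 2, 2, 4))
  expect_true(m$ties)
  expect_lt(m$rho, 1)
  expect_error(stage_monotonicity(c(1, 2)), "3 stages")
})
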