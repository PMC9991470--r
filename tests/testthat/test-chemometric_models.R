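# PCA / PLS-DA / LS-SVM: hand and closed-form oracles, structural
# invariants, limit behaviour.

test_that("PCA: rank-1 data, hand SVD, and variance conservation", {
  # rank-1: PC1 explains everything
  X1 <- outer(c(1, 2, 3, 4), c(2, -1, 0.5))
  m1 <- pca_fit(X1, 1)
  expect_equal(m1$explained[1], 1, tolerance = 1e-12)

  # 4-point hand fixture vs direct SVD of the centered matrix
  X <- rbind(c(1, 1), c(-1, -1), c(0.1, -0.1), c(-0.1, 0.1))
  m <- pca_fit(X, 2)
  sv <- svd(scale(X, scale = FALSE))
  expect_equal(abs(m$loadings), abs(sv$v), tolerance = 1e-12)
  expect_equal(m$explained_all, sv$d^2 / sum(sv$d^2), tolerance = 1e-12)
  # by hand: centered scatter [[2.02, 1.98], [1.98, 2.02]], eigenvalues
  # 2.02 +/- 1.98 = {4.00, 0.04}; PC1 is the (1,1)/sqrt(2) diagonal
  expect_equal(abs(m$loadings[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(m$explained[1], 4.00 / 4.04, tolerance = 1e-12)

  set.seed(41)
  Xr <- matrix(rnorm(15 * 6), 15, 6)
  mr <- pca_fit(Xr, 4)
  expect_equal(sum(mr$explained_all), 1, tolerance = 1e-10)
  expect_false(is.unsorted(rev(mr$explained_all)))
  expect_equal(crossprod(mr$loadings), diag(4), tolerance = 1e-10)
  expect_equal(predict(mr, Xr), mr$scores, tolerance = 1e-12)

  expect_error(pca_fit(Xr, 7), "outside")
  expect_error(pca_fit(matrix(3, 5, 2), 1), "zero-variance")
})

test_that("PLS-DA at full rank matches the OLS solution", {
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 5), 20, 5)
    y <- sample(rep(c("free-range", "caged"), 10))
    fit <- plsda_fit(X, y, lv = 5)
    oracle <- ols_coded(X, ifelse(y == "free-range", 1, -1))
    expect_equal(fit$coef, unname(oracle$coef), tolerance = 1e-8)
    expect_equal(fit$intercept, unname(oracle$intercept), tolerance = 1e-8)
  }
})

test_that("PLS-DA: separable 1-D limit, score orthogonality, rank guard, tie rule", {
  y <- rep(c("free-range", "caged"), each = 10)
  x <- cbind(c(rnorm(10, 3, 0.1), rnorm(10, -3, 0.1)))
  fit <- plsda_fit(x, y, 1)
  expect_identical(plsda_predict(fit, x)$class, y)

  set.seed(42)
  X <- matrix(rnorm(30 * 6), 30, 6)
  yy <- sample(rep(c("free-range", "caged"), 15))
  m <- plsda_fit(X, yy, 4)
  G <- crossprod(m$T)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)

  expect_error(plsda_fit(X, yy, 7), "exceeds rank")
  expect_error(plsda_fit(X, rep("free-range", 30), 2), "both classes")

  # decision value exactly 0 goes to the positive class
  fit0 <- plsda_fit(x, y, 1)
  fit0$coef[] <- 0; fit0$intercept <- 0
  expect_true(all(plsda_predict(fit0, x)$class == "free-range"))
})

test_that("PLS-DA model JSON round-trip preserves predictions", {
  set.seed(43)
  X <- matrix(rnorm(24 * 4), 24, 4)
  y <- rep(c("free-range", "caged"), 12)
  fit <- plsda_fit(X, y, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_plsda_model(fit, path)
  back <- read_plsda_model(path)
  expect_equal(plsda_predict(back, X)$score, plsda_predict(fit, X)$score)
})

test_that("LS-SVM solves its KKT system exactly (brute-force oracle)", {
  set.seed(44)
  X <- matrix(rnorm(4 * 2), 4, 2)
  y <- c("free-range", "free-range", "caged", "caged")
  fit <- lssvm_fit(X, y, sigma2 = 1, gamma = 10)
  oracle <- lssvm_brute(X, c(1, 1, -1, -1), sigma2 = 1, gamma = 10)
  expect_equal(fit$alpha, unname(oracle$alpha), tolerance = 1e-10)
  expect_equal(fit$b, unname(oracle$b), tolerance = 1e-10)
  expect_lt(fit$kkt_residual, 1e-10)
  expect_lt(abs(sum(fit$alpha)), 1e-8)
})

test_that("LS-SVM: symmetric data gives zero bias; huge gamma interpolates", {
  set.seed(45)
  Xp <- matrix(rnorm(6 * 3), 6, 3)
  X <- rbind(Xp, -Xp)
  y <- rep(c(1, -1), each = 6)
  fit <- lssvm_fit(X, y, sigma2 = 2, gamma = 5)
  expect_lt(abs(fit$b), 1e-10)

  X2 <- matrix(rnorm(10 * 2), 10, 2)
  y2 <- rep(c(1, -1), 5)
  interp <- lssvm_fit(X2, y2, sigma2 = 1, gamma = 1e8)
  expect_equal(lssvm_predict(interp, X2)$score, y2, tolerance = 1e-4)
})

test_that("LS-SVM decision values are invariant to training order", {
  set.seed(46)
  X <- matrix(rnorm(20 * 4), 20, 4)
  y <- rep(c("free-range", "caged"), 10)
  Xnew <- matrix(rnorm(5 * 4), 5, 4)
  f1 <- lssvm_predict(lssvm_fit(X, y, 700, 5), Xnew)$score
  perm <- sample(20)
  f2 <- lssvm_predict(lssvm_fit(X[perm, ], y[perm], 700, 5), Xnew)$score
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("LS-SVM model JSON round-trip preserves predictions", {
  set.seed(47)
  X <- matrix(rnorm(16 * 3), 16, 3)
  y <- rep(c("free-range", "caged"), 8)
  fit <- lssvm_fit(X, y, 700, 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_lssvm_model(fit, path)
  back <- read_lssvm_model(path)
  expect_equal(lssvm_predict(back, X)$score, lssvm_predict(fit, X)$score,
               tolerance = 1e-12)
})
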