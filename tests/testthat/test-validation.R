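# Confusion counts, the sensitivity/specificity/accuracy worked examples,
# MCCV error estimation against an exhaustive oracle, and grid search.

test_that("confusion tabulates the reference worked examples", {
  y <- rep(c("free-range", "caged"), c(45, 41))
  all_right <- confusion(y, y)
  expect_equal(unclass(all_right), list(TP = 45L, FN = 0L, TN = 41L, FP = 0L))

  flipped <- confusion(y, ifelse(y == "free-range", "caged", "free-range"))
  expect_equal(unclass(flipped), list(TP = 0L, FN = 45L, TN = 0L, FP = 41L))

  pred <- y
  pred[c(1:4)] <- "caged"            # 4 false negatives
  pred[45 + 1:3] <- "free-range"     # 3 false positives
  expect_equal(unclass(confusion(y, pred)), list(TP = 41L, FN = 4L, TN = 38L, FP = 3L))

  expect_error(confusion(y, rep("organic", 86)), "unknown class")
  expect_error(confusion(y, y[-1]), "lengths differ")
})

test_that("metrics reproduce the reference worked examples exactly", {
  m1 <- class_metrics(list(TP = 41, FN = 4, TN = 38, FP = 3))
  expect_equal(unname(m1$percent), c(91.1, 92.7, 91.9))   # sens, spec, accu

  m2 <- class_metrics(list(TP = 43, FN = 2, TN = 39, FP = 2))
  expect_equal(unname(m2$percent), c(95.6, 95.1, 95.3))

  m3 <- class_metrics(list(TP = 45, FN = 0, TN = 41, FP = 0))
  expect_equal(unname(m3$percent), c(100, 100, 100))

  # empty class: metric reported as NA, never silent 0/0
  m4 <- class_metrics(list(TP = 0, FN = 0, TN = 10, FP = 2))
  expect_true(is.na(m4$sensitivity))
  expect_false(is.na(m4$specificity))
})

test_that("accuracy equals the class-size-weighted mix of sens and spec", {
  set.seed(51)
  for (i in 1:25) {
    tp <- sample(0:20, 1); fn <- sample(0:20, 1)
    tn <- sample(0:20, 1); fp <- sample(0:20, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    m <- class_metrics(list(TP = tp, FN = fn, TN = tn, FP = fp))
    P <- tp + fn; N <- tn + fp
    expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("MCCV matches analytic expectations for trivial classifiers", {
  set.seed(52)
  n <- 60
  y <- rep(c("free-range", "caged"), each = n / 2)
  X <- cbind(rnorm(n))
  # constant-positive classifier on balanced data: error 1/2 exactly under
  # class-stratified validation draws (9 + 9 per split)
  const_fit <- function(X, y) structure(list(), class = "const")
  const_pred <- function(model, X) rep("free-range", nrow(X))
  err <- mccv_error(X, y, const_fit, const_pred, n_splits = 40, seed = 1)
  expect_equal(as.numeric(err), 0.5, tolerance = 1e-12)

  # perfectly separable data: error 0
  Xs <- cbind(ifelse(y == "free-range", 5, -5) + rnorm(n, sd = 0.1))
  err0 <- mccv_error(Xs, y, function(X, y) plsda_fit(X, y, 1), plsda_predict,
                     n_splits = 40, seed = 2)
  expect_equal(as.numeric(err0), 0)
})

test_that("MCCV of a fixed classifier agrees with exhaustive enumeration", {
  # n = 10 (5 + 5), stratified 70/30 -> validation = 1 + 1; enumerate all
  # 5 x 5 validation pairs exactly and compare the Monte Carlo estimate
  set.seed(53)
  x <- c(rnorm(5, 1.0), rnorm(5, -1.0))
  y <- rep(c("free-range", "caged"), each = 5)
  classify <- function(v) ifelse(v >= 0, "free-range", "caged")
  exact <- mean(vapply(1:5, function(i) {
    vapply(6:10, function(j) mean(classify(x[c(i, j)]) != y[c(i, j)]), 0)
  }, numeric(5)))

  fixed_fit <- function(X, y) structure(list(), class = "fixed")
  fixed_pred <- function(model, X) classify(X[, 1])
  n_splits <- 400
  est <- mccv_error(cbind(x), y, fixed_fit, fixed_pred,
                    n_splits = n_splits, seed = 3, autoscale = FALSE)
  se <- stats::sd(attr(est, "per_split")) / sqrt(n_splits)
  expect_lt(abs(as.numeric(est) - exact), 3 * max(se, 1e-6))
})

test_that("grid search selects by minimum error with deterministic shared splits", {
  set.seed(54)
  n <- 50
  y <- rep(c("free-range", "caged"), each = n / 2)
  X <- cbind(ifelse(y == "free-range", 1, -1) + rnorm(n), rnorm(n))

  g1 <- grid_search("plsda", X, y, grid = c(1, 2), n_splits = 25, seed = 7)
  g2 <- grid_search("plsda", X, y, grid = c(1, 2), n_splits = 25, seed = 7)
  expect_identical(g1$surface, g2$surface)
  expect_equal(g1$selected$mccver, min(g1$surface$mccver))

  single <- grid_search("lssvm", X, y, grid = data.frame(sigma2 = 700, gamma = 5),
                        n_splits = 10, seed = 8)
  expect_equal(single$selected$sigma2, 700)

  expect_error(grid_search("plsda", X, y, grid = integer(0)), "empty")
})

test_that("tie-breaking prefers the simplest model", {
  surface_order <- function(g) g$selected
  # force ties by using trivially separable data (every candidate errs 0)
  set.seed(56)
  y <- rep(c("free-range", "caged"), each = 20)
  X <- cbind(ifelse(y == "free-range", 10, -10) + rnorm(40, sd = 0.01),
             rnorm(40), rnorm(40))
  g <- grid_search("plsda", X, y, grid = c(1, 2, 3), n_splits = 10, seed = 9)
  expect_equal(g$selected$lv, 1)
  gl <- grid_search("lssvm", X, y,
                    grid = expand.grid(sigma2 = c(10, 700), gamma = c(0.5, 5)),
                    n_splits = 10, seed = 10)
  expect_equal(gl$selected$gamma, 0.5)
  expect_equal(gl$selected$sigma2, 700)  # largest sigma2 among ties
})

test_that("pure-noise features never beat the informative set (20 seeds)", {
  # dominance experiment, rate established before freezing: the same
  # classifier evaluated on informative features vs informative + 30 noise
  # columns never has a larger MCCVER on the informative set
  for (s in 1:20) {
    set.seed(s)
    n <- 60
    y <- rep(c("free-range", "caged"), each = n / 2)
    shift <- ifelse(y == "free-range", 0.9, -0.9)
    Xi <- cbind(shift + rnorm(n), shift * 0.8 + rnorm(n))
    Xn <- cbind(Xi, matrix(rnorm(n * 30), n, 30))
    fit <- function(X, yy) plsda_fit(X, yy, 2)
    ei <- mccv_error(Xi, y, fit, plsda_predict, n_splits = 50, seed = s)
    en <- mccv_error(Xn, y, fit, plsda_predict, n_splits = 50, seed = s)
    expect_lte(as.numeric(ei), as.numeric(en))
  }
})

test_that("MCCVER is invariant to feature order", {
  set.seed(55)
  n <- 40
  y <- rep(c("free-range", "caged"), each = n / 2)
  X <- cbind(ifelse(y == "free-range", 1, -1) + rnorm(n), rnorm(n), rnorm(n))
  fit <- function(X, yy) plsda_fit(X, yy, 2)
  e1 <- mccv_error(X, y, fit, plsda_predict, n_splits = 30, seed = 4)
  e2 <- mccv_error(X[, c(3, 1, 2)], y, fit, plsda_predict, n_splits = 30, seed = 4)
  expect_equal(as.numeric(e1), as.numeric(e2), tolerance = 1e-12)
})
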