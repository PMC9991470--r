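# Model assessment: confusion-matrix metrics (free-range = positive class),
# Monte Carlo cross-validation (MCCV) error rates, and grid search over
# candidate model parameters with a shared split sequence so candidates are
# compared on identical resamples.

#' Confusion counts for the two-class problem
#'
#' Free-range eggs are the positive class, caged eggs the negative class.
#'
#' @param y_true,y_pred equal-length label vectors drawn from
#'   `"free-range"`/`"caged"` (numeric +/-1 also accepted).
#' @return A `confusion_counts` list: `TP`, `FN`, `TN`, `FP`.
#' @export
#' @examples
#' confusion(rep(c("free-range", "caged"), c(2, 2)),
#'           c("free-range", "caged", "caged", "free-range"))
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort_fmt("y_true and y_pred lengths differ")
  t_ <- code_classes(y_true)$y
  p_ <- code_classes(y_pred)$y
  structure(list(TP = sum(t_ == 1 & p_ == 1),
                 FN = sum(t_ == 1 & p_ == -1),
                 TN = sum(t_ == -1 & p_ == -1),
                 FP = sum(t_ == -1 & p_ == 1)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Sens = TP/(TP+FN), Spec = TN/(TN+FP), Accu = (TP+TN)/n. Each metric is
#' returned as a fraction and as a percentage rounded half-up to 1 decimal
#' (the presentation convention of the reference study). An empty class
#' makes the corresponding metric `NA` (never a silent 0/0).
#'
#' @param counts a `confusion_counts` (or list with TP/FN/TN/FP).
#' @return A `class_metrics` list: `sensitivity`, `specificity`,
#'   `accuracy` (fractions) and `percent` (named, 1-decimal).
#' @export
#' @examples
#' class_metrics(list(TP = 41, FN = 4, TN = 38, FP = 3))$percent
class_metrics <- function(counts) {
  with(counts, {
    if (any(c(TP, FN, TN, FP) < 0)) abort_fmt("confusion counts must be non-negative")
    sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
    n <- TP + FN + TN + FP
    accu <- if (n > 0) (TP + TN) / n else NA_real_
    structure(list(sensitivity = sens, specificity = spec, accuracy = accu,
                   percent = c(sensitivity = round_half_up(100 * sens, 1),
                               specificity = round_half_up(100 * spec, 1),
                               accuracy = round_half_up(100 * accu, 1))),
              class = "class_metrics")
  })
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%\n",
              x$percent["accuracy"], x$percent["sensitivity"], x$percent["specificity"]))
  invisible(x)
}

# internal: draw the MCCV split sequence. Stratified by class so the
# train fraction holds within class (unstratified draws can produce
# single-class training sets at these sizes); validation size is rounded
# down per class for deterministic sizes.
mccv_splits <- function(y, n_splits, train_frac, seed) {
  cc <- code_classes(y)$y
  idx_pos <- which(cc == 1); idx_neg <- which(cc == -1)
  if (!length(idx_pos) || !length(idx_neg)) abort_fmt("both classes must be present")
  nv_pos <- floor(length(idx_pos) * (1 - train_frac))
  nv_neg <- floor(length(idx_neg) * (1 - train_frac))
  if (nv_pos + nv_neg == 0) abort_fmt("validation sets are empty at train_frac = %g", train_frac)
  set.seed(stage_seed(seed, "mccv-splits"))
  lapply(seq_len(n_splits), function(s) {
    val <- c(if (nv_pos) sample(idx_pos, nv_pos), if (nv_neg) sample(idx_neg, nv_neg))
    list(train = setdiff(seq_along(cc), val), val = val)
  })
}

# internal: labels out of whatever a predict function returned
as_pred_labels <- function(pred) {
  if (is.list(pred) && !is.null(pred$class)) pred$class else pred
}

#' Monte Carlo cross-validation error rate
#'
#' Repeated stratified random train/validation splits (reference setting:
#' 100 splits at 70/30); the reported MCCVER pools predictions (total
#' misclassified / total predicted) across splits. Column autoscaling, when
#' requested, is refit on each split's training rows only, so no validation
#' statistic leaks into the model.
#'
#' @param X numeric n x p matrix (pre-autoscaling representation).
#' @param y class labels.
#' @param fit_fun `function(X_train, y_train) -> model`.
#' @param predict_fun `function(model, X_val) -> labels` (or a list with a
#'   `class` component, as [plsda_predict()]/[lssvm_predict()] return).
#' @param n_splits number of random splits (default 100).
#' @param train_frac training fraction (default 0.7).
#' @param seed split-sequence seed.
#' @param autoscale refit column scaling inside each split (default TRUE).
#' @return The pooled error rate, with attributes `per_split` (individual
#'   split error rates), `n_splits`, `train_frac`, `seed`, `convention`.
#' @export
mccv_error <- function(X, y, fit_fun, predict_fun,
                       n_splits = 100, train_frac = 0.7, seed = 1,
                       autoscale = TRUE) {
  X <- as.matrix(X)
  splits <- mccv_splits(y, n_splits, train_frac, seed)
  wrong <- total <- 0
  per_split <- numeric(length(splits))
  for (s in seq_along(splits)) {
    tr <- splits[[s]]$train; va <- splits[[s]]$val
    Xtr <- X[tr, , drop = FALSE]; Xva <- X[va, , drop = FALSE]
    if (autoscale) {
      sp <- autoscale_fit(Xtr, subset_id = "mccv-train")
      Xtr <- autoscale_apply(Xtr, sp); Xva <- autoscale_apply(Xva, sp)
    }
    model <- fit_fun(Xtr, y[tr])
    pred <- as_pred_labels(predict_fun(model, Xva))
    err <- code_classes(pred)$y != code_classes(y[va])$y
    wrong <- wrong + sum(err); total <- total + length(err)
    per_split[s] <- mean(err)
  }
  structure(wrong / total, per_split = per_split, n_splits = n_splits,
            train_frac = train_frac, seed = seed, convention = "pooled")
}

#' Default tuning grids
#'
#' Latent-variable counts 1..10 for PLS-DA; the (sigma2, gamma) lattice
#' {10, 50, 100, 300, 500, 700, 1000, 3000} x {0.5, 1, 5, 10, 50, 100} for
#' the LS-SVM, covering the reference optima LV = 4 and (700, 5).
#'
#' @return Integer vector (`default_lv_grid`) or data frame with columns
#'   `sigma2`, `gamma` (`default_lssvm_grid`).
#' @export
default_lv_grid <- function() 1:10

#' @rdname default_lv_grid
#' @export
default_lssvm_grid <- function() {
  expand.grid(sigma2 = c(10, 50, 100, 300, 500, 700, 1000, 3000),
              gamma = c(0.5, 1, 5, 10, 50, 100))
}

#' MCCV grid search for model parameters
#'
#' Evaluates every candidate on one shared split sequence (a paired
#' comparison: all candidates see identical resamples), refitting the
#' column scaling per split. The selected candidate attains the minimal
#' MCCVER; ties go to the simplest model (smallest LV; for the LS-SVM
#' smallest gamma, then largest sigma2).
#'
#' @param family `"plsda"` (grid = integer LVs) or `"lssvm"` (grid = data
#'   frame with columns `sigma2`, `gamma`).
#' @param X,y training data (pre-autoscaling representation).
#' @param grid candidate parameters; defaults to [default_lv_grid()] /
#'   [default_lssvm_grid()].
#' @param n_splits,train_frac,seed,autoscale as in [mccv_error()].
#' @return An `mccv_grid`: data frame `surface` (candidate + `mccver`),
#'   `selected` (row of the surface), `family`, and the MCCV settings.
#' @export
grid_search <- function(family = c("plsda", "lssvm"), X, y, grid = NULL,
                        n_splits = 100, train_frac = 0.7, seed = 1,
                        autoscale = TRUE) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (is.null(grid)) grid <- if (family == "plsda") default_lv_grid() else default_lssvm_grid()
  n_cand <- if (family == "plsda") length(grid) else nrow(grid)
  if (!n_cand) abort_fmt("empty parameter grid")

  splits <- mccv_splits(y, n_splits, train_frac, seed)
  # pre-scale each split once; candidates share the resamples and scaling
  prepared <- lapply(splits, function(sp) {
    Xtr <- X[sp$train, , drop = FALSE]; Xva <- X[sp$val, , drop = FALSE]
    if (autoscale) {
      pars <- autoscale_fit(Xtr, subset_id = "mccv-train")
      Xtr <- autoscale_apply(Xtr, pars); Xva <- autoscale_apply(Xva, pars)
    }
    list(Xtr = Xtr, ytr = y[sp$train], Xva = Xva, yva = y[sp$val])
  })
  eval_candidate <- function(fit_fun, predict_fun) {
    wrong <- total <- 0
    for (pr in prepared) {
      model <- fit_fun(pr$Xtr, pr$ytr)
      pred <- as_pred_labels(predict_fun(model, pr$Xva))
      wrong <- wrong + sum(code_classes(pred)$y != code_classes(pr$yva)$y)
      total <- total + length(pr$yva)
    }
    wrong / total
  }

  if (family == "plsda") {
    mccver <- vapply(grid, function(lv) {
      eval_candidate(function(Xt, yt) plsda_fit(Xt, yt, lv), plsda_predict)
    }, numeric(1))
    surface <- data.frame(lv = grid, mccver = mccver)
    ord <- order(surface$mccver, surface$lv)
  } else {
    mccver <- vapply(seq_len(nrow(grid)), function(i) {
      eval_candidate(function(Xt, yt) lssvm_fit(Xt, yt, grid$sigma2[i], grid$gamma[i]),
                     lssvm_predict)
    }, numeric(1))
    surface <- data.frame(grid, mccver = mccver)
    ord <- order(surface$mccver, surface$gamma, -surface$sigma2)
  }
  structure(list(family = family, surface = surface,
                 selected = surface[ord[1], , drop = FALSE],
                 n_splits = n_splits, train_frac = train_frac, seed = seed,
                 convention = "pooled"),
            class = "mccv_grid")
}

#' @export
print.mccv_grid <- function(x, ...) {
  cat(sprintf("<mccv_grid> %s, %d candidate(s), %d splits at %.0f/%.0f\n",
              x$family, nrow(x$surface), x$n_splits,
              100 * x$train_frac, 100 * (1 - x$train_frac)))
  cat("selected: "); print(x$selected, row.names = FALSE)
  invisible(x)
}

#' Write an MCCV surface as CSV (candidate, MCCVER)
#'
#' @param grid an `mccv_grid`.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_mccv_grid <- function(grid, path) {
  utils::write.csv(grid$surface, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
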