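# PLS-DA: partial least squares regression (PLS1, NIPALS) on a +/-1 coded
# class response, thresholded at zero. The single-response recursion is
# used because the problem is two-class; classical X-deflation per
# component, y not deflated.

#' Fit a PLS-DA model
#'
#' @param X numeric n x p training matrix (typically autoscaled on the
#'   training set).
#' @param y class labels (`"free-range"`/`"caged"`, coded +1/-1 internally;
#'   numeric +/-1 also accepted). Both classes must be present.
#' @param lv number of latent variables, `1 <= lv <= rank(X centered)`.
#'   Exceeding the rank is an error, not a silent truncation.
#' @return A `plsda_model` with X-weights `W`, X-loadings `P`, y-loadings
#'   `Q`, X-scores `T` (mutually orthogonal), regression coefficients
#'   `coef` and `intercept` (on the original column scale of `X`), the
#'   class-code map and the decision threshold (0).
#' @details At `lv = rank(X)` the coefficient vector equals the ordinary
#'   least-squares solution on the coded response.
#' @export
plsda_fit <- function(X, y, lv) {
  X <- as.matrix(X)
  cc <- code_classes(y)
  if (length(unique(cc$y)) < 2) abort_fmt("both classes must be present in training data")
  if (length(cc$y) != nrow(X)) abort_fmt("X and y lengths differ")
  xm <- colMeans(X)
  ym <- mean(cc$y)
  Xc <- sweep(X, 2, xm, `-`)
  yc <- cc$y - ym
  rk <- qr(Xc)$rank
  check_scalar_num(lv, "lv", lower = 1)
  if (lv > rk) abort_fmt("lv = %d exceeds rank(X) = %d", lv, rk)
  lv <- as.integer(lv)

  p <- ncol(X)
  W <- P <- matrix(0, p, lv)
  Q <- numeric(lv)
  Tm <- matrix(0, nrow(X), lv)
  Xd <- Xc
  for (a in seq_len(lv)) {
    w <- crossprod(Xd, yc)
    w <- w / sqrt(sum(w^2))
    t <- Xd %*% w
    tt <- sum(t^2)
    pvec <- crossprod(Xd, t) / tt
    q <- sum(yc * t) / tt
    Xd <- Xd - t %*% t(pvec)
    W[, a] <- w; P[, a] <- pvec; Q[a] <- q; Tm[, a] <- t
  }
  B <- W %*% solve(crossprod(P, W), Q)
  structure(list(lv = lv, W = W, P = P, Q = Q, T = Tm,
                 coef = as.numeric(B),
                 intercept = ym - sum(xm * B),
                 x_center = xm, y_center = ym,
                 class_map = cc$map, threshold = 0),
            class = "plsda_model")
}

#' Predict with a PLS-DA model
#'
#' @param model a `plsda_model`.
#' @param X matrix of new samples on the training column scale.
#' @return `list(score = <continuous decision value>, class = <label>)`;
#'   a score of exactly 0 is assigned to the positive (free-range) class.
#' @export
plsda_predict <- function(model, X) {
  X <- as.matrix(X)
  score <- as.numeric(X %*% model$coef + model$intercept)
  list(score = score, class = decode_classes(score, model$class_map))
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d latent variable(s), %d predictors\n",
              x$lv, length(x$coef)))
  invisible(x)
}

#' @export
predict.plsda_model <- function(object, newdata, ...) plsda_predict(object, newdata)

#' Serialize / restore a PLS-DA model (JSON)
#'
#' @param model a `plsda_model`.
#' @param path file path.
#' @return `path` invisibly / the restored model.
#' @export
write_plsda_model <- function(model, path) {
  obj <- lapply(unclass(model), function(z) if (is.matrix(z)) unclass(as.data.frame(z)) else z)
  obj$class_map <- as.list(model$class_map)   # keep names through JSON
  obj$x_center <- as.list(model$x_center)
  obj$schema <- "eggchem/plsda/1"
  jsonlite::write_json(obj, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_plsda_model
#' @export
read_plsda_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(lv = o$lv, W = as.matrix(as.data.frame(o$W)),
                 P = as.matrix(as.data.frame(o$P)), Q = o$Q,
                 T = as.matrix(as.data.frame(o$T)),
                 coef = o$coef, intercept = o$intercept,
                 x_center = unlist(o$x_center), y_center = o$y_center,
                 class_map = unlist(o$class_map), threshold = o$threshold),
            class = "plsda_model")
}
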