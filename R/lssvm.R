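# Least-squares SVM with an RBF kernel. Training reduces to one symmetric
# linear system (the KKT conditions of the equality-constrained squared-loss
# problem):
#
#   [ 0   1^T          ] [ b     ]   [ 0 ]
#   [ 1   K + I/gamma  ] [ alpha ] = [ y ]
#
# with K(u, v) = exp(-||u - v||^2 / sigma2). The tuned kernel magnitude in
# the reference workflow (700) is read as sigma^2; the convention is stored
# on the model so either reading is reproducible.

rbf_kernel <- function(A, B, sigma2) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0  # numerical guard
  exp(-d2 / sigma2)
}

#' Fit an LS-SVM classifier
#'
#' @param X numeric n x p training matrix.
#' @param y class labels (`"free-range"`/`"caged"` or +/-1); both classes
#'   required.
#' @param sigma2 RBF kernel width parameter (the squared length scale in
#'   `exp(-d^2 / sigma2)`), > 0.
#' @param gamma regularization parameter, > 0 (larger = closer fit to the
#'   training labels).
#' @return An `lssvm_model`: dual coefficients `alpha` (one per training
#'   sample, summing to 0), bias `b`, the kernel parameters, the stored
#'   training inputs, the class-code map, and the KKT residual of the
#'   solved system.
#' @export
lssvm_fit <- function(X, y, sigma2, gamma) {
  X <- as.matrix(X)
  cc <- code_classes(y)
  if (length(unique(cc$y)) < 2) abort_fmt("both classes must be present in training data")
  if (length(cc$y) != nrow(X)) abort_fmt("X and y lengths differ")
  check_scalar_num(sigma2, "sigma2", lower = .Machine$double.eps)
  check_scalar_num(gamma, "gamma", lower = .Machine$double.eps)
  n <- nrow(X)
  K <- rbf_kernel(X, X, sigma2)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / gamma))
  rhs <- c(0, cc$y)
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    abort_fmt("singular LS-SVM system (rcond = %.3e): near-duplicate points at extreme gamma? [%s]",
              rcond(A), conditionMessage(e))
  })
  structure(list(alpha = sol[-1], b = sol[1],
                 sigma2 = sigma2, gamma = gamma,
                 kernel = "rbf(exp(-d^2/sigma2))",
                 X_train = X, class_map = cc$map,
                 kkt_residual = max(abs(A %*% sol - rhs))),
            class = "lssvm_model")
}

#' Predict with an LS-SVM model
#'
#' Decision value `f(x) = sum_i alpha_i K(x, x_i) + b`; class is its sign,
#' with 0 assigned to the positive (free-range) class.
#'
#' @param model an `lssvm_model`.
#' @param X matrix of new samples on the training column scale.
#' @return `list(score = <decision values>, class = <labels>)`.
#' @export
lssvm_predict <- function(model, X) {
  K <- rbf_kernel(as.matrix(X), model$X_train, model$sigma2)
  score <- as.numeric(K %*% model$alpha + model$b)
  list(score = score, class = decode_classes(score, model$class_map))
}

#' @export
print.lssvm_model <- function(x, ...) {
  cat(sprintf("<lssvm_model> n = %d, sigma2 = %g, gamma = %g, KKT residual = %.2e\n",
              length(x$alpha), x$sigma2, x$gamma, x$kkt_residual))
  invisible(x)
}

#' @export
predict.lssvm_model <- function(object, newdata, ...) lssvm_predict(object, newdata)

#' Serialize / restore an LS-SVM model (JSON)
#'
#' @param model an `lssvm_model`.
#' @param path file path.
#' @return `path` invisibly / the restored model.
#' @export
write_lssvm_model <- function(model, path) {
  obj <- list(schema = "eggchem/lssvm/1", alpha = model$alpha, b = model$b,
              sigma2 = model$sigma2, gamma = model$gamma, kernel = model$kernel,
              X_train = unclass(as.data.frame(model$X_train)),
              class_map = as.list(model$class_map),
              kkt_residual = model$kkt_residual)
  jsonlite::write_json(obj, path, digits = NA, pretty = TRUE, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lssvm_model
#' @export
read_lssvm_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(alpha = o$alpha, b = o$b, sigma2 = o$sigma2, gamma = o$gamma,
                 kernel = o$kernel, X_train = as.matrix(as.data.frame(o$X_train)),
                 class_map = unlist(o$class_map), kkt_residual = o$kkt_residual),
            class = "lssvm_model")
}
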