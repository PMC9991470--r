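# Principal component analysis by singular value decomposition of the
# column-centered data; used for exploratory visualisation of the rescaled
# element profiles (score and loading plots).

#' Fit a PCA model
#'
#' @param X numeric n x p matrix. Centering is performed internally and the
#'   centers recorded; pass already-autoscaled data for the usual
#'   correlation-scale PCA of element profiles.
#' @param k number of components to retain, `1 <= k <= min(n - 1, p)`.
#' @return A `pca_model`: `loadings` (p x k, orthonormal), `scores`
#'   (n x k), `explained` (length-k fractions of total variance),
#'   `explained_all` (all `min(n-1, p)` fractions, summing to 1),
#'   `center`, and `k`.
#' @export
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' m <- pca_fit(X, 2)
#' sum(m$explained_all)  # 1
pca_fit <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  kmax <- min(n - 1L, p)
  check_scalar_num(k, "k", lower = 1, upper = kmax)
  k <- as.integer(k)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr, `-`)
  total <- sum(Xc^2)
  if (total == 0) abort_fmt("zero-variance input: PCA undefined")
  sv <- svd(Xc, nu = 0, nv = kmax)
  frac <- sv$d[seq_len(kmax)]^2 / sum(sv$d^2)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(X)
  structure(list(loadings = loadings,
                 scores = Xc %*% loadings,
                 explained = frac[seq_len(k)],
                 explained_all = frac,
                 center = ctr, k = k),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d component(s); explained: %s\n", x$k,
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' Project new samples onto a fitted PCA
#'
#' @param object a `pca_model`.
#' @param newdata matrix on the same variable scale as the training data.
#' @param ... unused.
#' @return Score matrix (n x k).
#' @export
predict.pca_model <- function(object, newdata, ...) {
  sweep(as.matrix(newdata), 2, object$center, `-`) %*% object$loadings
}
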