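# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (explicit loops, closed forms) so they stay
# independent of the vectorized implementation paths they check.

# Brute-force Kennard-Stone: explicit pair scan for the initial pair
# (lexicographic tie-break) and explicit candidate loops thereafter
# (lowest-index tie-break via strict >).
ks_brute_force <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  best <- c(NA, NA); bd <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > bd) { bd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_select) {
    bv <- -Inf; bi <- NA
    for (cand in setdiff(seq_len(n), sel)) {
      mv <- min(D[cand, sel])
      if (mv > bv) { bv <- mv; bi <- cand }
    }
    sel <- c(sel, bi)
  }
  sel
}

# Fine directional grid for 2-D Stahel-Donoho outlyingness: directions
# (cos t, sin t) over a half-circle (signs are irrelevant to |.|).
sde_grid_2d <- function(X, n_angles = 1e5) {
  th <- seq(0, pi, length.out = n_angles)
  A <- cbind(cos(th), sin(th))
  P <- X %*% t(A)
  med <- apply(P, 2, stats::median)
  scl <- apply(P, 2, stats::mad)
  ok <- scl > 0
  Z <- abs(sweep(P[, ok, drop = FALSE], 2, med[ok], `-`))
  Z <- sweep(Z, 2, scl[ok], `/`)
  apply(Z, 1, max)
}

# Ordinary least squares with intercept on a +/-1 coded response.
ols_coded <- function(X, y01) {
  fit <- stats::lm.fit(cbind(1, X), y01)
  list(intercept = fit$coefficients[1], coef = fit$coefficients[-1])
}

# Direct (loop-built) LS-SVM KKT system solve.
lssvm_brute <- function(X, y01, sigma2, gamma) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) K[i, j] <- exp(-sum((X[i, ] - X[j, ])^2) / sigma2)
  A <- matrix(0, n + 1, n + 1)
  A[1, 2:(n + 1)] <- 1
  A[2:(n + 1), 1] <- 1
  A[2:(n + 1), 2:(n + 1)] <- K + diag(n) / gamma
  sol <- solve(A, c(0, y01))
  list(b = sol[1], alpha = sol[-1])
}

# Small profile-table fixture built in code: deterministic values, both
# classes, valid against the reference panel.
tiny_profile_table <- function(n_per_class = 3, seed = 42) {
  generate_profiles(cfg = generator_config(
    n_per_class = c("free-range" = n_per_class, "caged" = n_per_class),
    seed = seed))
}

# Scaled-down pipeline config for fast orchestration tests; `...`
# overrides any default field.
small_pipeline_config <- function(..., seed = 11) {
  args <- list(
    n_per_class = c("free-range" = 30, "caged" = 28),
    n_projections = 200,
    n_train = c("free-range" = 15, "caged" = 15),
    lv_grid = 1:3,
    lssvm_grid = data.frame(sigma2 = c(100, 700), gamma = c(1, 5)),
    n_splits = 20,
    seed = seed)
  dots <- list(...)
  for (nm in names(dots)) args[[nm]] <- dots[[nm]]
  do.call(pipeline_config, args)
}
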