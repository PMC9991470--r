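# Preprocessing: the two-stage rescaling used throughout the workflow
# (row-wise division by digested sample weight, then column-wise
# autoscaling to zero mean / unit variance), plus the 3-sigma blank-based
# detection limit and its censoring rule.

#' Estimate a detection limit from replicate blank measurements
#'
#' DL = 3 x sample SD of the blank signals (n - 1 denominator), in
#' concentration units. The reference protocol uses 11 blank replicates.
#'
#' @param blank_signals numeric vector of replicate blank readings.
#' @param n_required expected replicate count (default 11); a different
#'   length is an error so silently under-replicated DLs cannot slip in.
#' @return The detection limit (scalar).
#' @export
#' @examples
#' estimate_detection_limit(rep(0, 11))  # zero-variance blanks -> DL 0
estimate_detection_limit <- function(blank_signals, n_required = 11) {
  if (length(blank_signals) < 2) abort_fmt("need at least 2 blank replicates")
  if (length(blank_signals) != n_required) {
    abort_fmt("expected %d blank replicates, got %d", n_required, length(blank_signals))
  }
  if (any(!is.finite(blank_signals))) abort_fmt("blank signals must be finite")
  3 * stats::sd(blank_signals)
}

#' Censor concentrations below the detection limit
#'
#' Values strictly below the per-element DL are replaced by 0 (the
#' nondetect convention of the reference table); values exactly at the DL
#' are retained. The number of censored cells is recorded in the returned
#' table's `censored_cells` attribute.
#'
#' @param table a [profile_table()].
#' @param panel panel carrying the DLs (default: the table's own).
#' @return The censored `profile_table`.
#' @export
censor_below_dl <- function(table, panel = attr(table, "panel") %||% element_panel()) {
  validate_profile_table(table, panel)
  X <- conc_matrix(table)
  below <- sweep(X, 2, panel$dl_ug_g, `<`) & X > 0
  X[below] <- 0
  out <- set_conc_matrix(table, X)
  attr(out, "censored_cells") <- sum(below)
  out
}

#' Row-wise rescaling by sample weight
#'
#' Divides each sample's element concentrations by its digested sample
#' weight, compensating for differences in the amount of shell digested.
#' Weights are retained in the `weight_g` column (metadata) unchanged.
#'
#' @param table a [profile_table()].
#' @return The rescaled `profile_table`.
#' @export
rescale_rowwise <- function(table) {
  validate_profile_table(table)
  set_conc_matrix(table, conc_matrix(table) / table$weight_g)
}

#' Fit column-wise autoscaling parameters
#'
#' "Unit variance" scaling in the full autoscaling sense: per-element
#' mean-centering and division by the standard deviation (n - 1
#' denominator), computed on a stated reference subset. For exploratory
#' stages (outlier screening, PCA) the reference is all samples; for
#' classifier training/testing it must be the training rows only, so no
#' test statistic leaks into the model.
#'
#' @param x numeric matrix, or a [profile_table()] (its concentration block
#'   is used).
#' @param subset integer/logical row index of the reference subset
#'   (default: all rows).
#' @param subset_id free-text record of what the subset was.
#' @return A `scaling_params` object: per-column `center` and `scale`, plus
#'   the reference record.
#' @export
autoscale_fit <- function(x, subset = NULL, subset_id = "all") {
  X <- if (inherits(x, "profile_table")) conc_matrix(x) else as.matrix(x)
  if (is.null(subset)) subset <- seq_len(nrow(X))
  Xr <- X[subset, , drop = FALSE]
  if (nrow(Xr) < 2) abort_fmt("autoscaling reference subset needs >= 2 samples")
  ctr <- colMeans(Xr)
  scl <- apply(Xr, 2, stats::sd)
  zero <- which(scl == 0)
  if (length(zero)) {
    nm <- colnames(Xr)[zero] %||% as.character(zero)
    abort_fmt("zero-variance column(s) on the reference subset: %s",
              paste(nm, collapse = ", "))
  }
  structure(list(center = ctr, scale = scl, subset_id = subset_id,
                 n_reference = nrow(Xr)),
            class = "scaling_params")
}

#' Apply (or invert) autoscaling
#'
#' @param x matrix or [profile_table()] to transform.
#' @param params a `scaling_params` from [autoscale_fit()].
#' @return Object of the same kind as `x`, transformed column-wise.
#' @export
autoscale_apply <- function(x, params) {
  if (inherits(x, "profile_table")) {
    return(set_conc_matrix(x, autoscale_apply(conc_matrix(x), params)))
  }
  X <- as.matrix(x)
  sweep(sweep(X, 2, params$center, `-`), 2, params$scale, `/`)
}

#' @rdname autoscale_apply
#' @export
autoscale_invert <- function(x, params) {
  X <- as.matrix(x)
  sweep(sweep(X, 2, params$scale, `*`), 2, params$center, `+`)
}

#' Serialize scaling parameters to JSON
#'
#' @param params a `scaling_params`.
#' @param path output path.
#' @return `path` invisibly; read back with [read_scaling_params()].
#' @export
write_scaling_params <- function(params, path) {
  obj <- list(center = as.list(params$center), scale = as.list(params$scale),
              subset_id = params$subset_id, n_reference = params$n_reference)
  jsonlite::write_json(obj, path, digits = NA, pretty = TRUE, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scaling_params
#' @export
read_scaling_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(center = unlist(obj$center), scale = unlist(obj$scale),
                 subset_id = obj$subset_id, n_reference = obj$n_reference),
            class = "scaling_params")
}
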