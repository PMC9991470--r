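# Robust outlier screening via Stahel-Donoho outlyingness approximated by
# random projections. The outlyingness of sample i is the largest robustly
# standardized deviation of its projection over the sampled directions:
#
#   out_i = max_a |x_i . a - median(X a)| / (1.4826 * MAD(X a))
#
# with directions a drawn uniformly on the unit sphere and MAD the raw
# (unscaled) median absolute deviation; 1.4826 is the consistency factor
# making the denominator estimate sigma under normality, so a cutoff of 3
# reads as a per-projection 3-sigma rule. Screening is applied within each
# husbandry class separately.

#' Stahel-Donoho outlyingness by random projections
#'
#' @param X numeric n x p matrix (already rescaled/scaled as desired);
#'   n >= 3.
#' @param n_projections number of random unit directions (default 1000).
#' @param seed integer seed making the direction set reproducible.
#' @return Numeric vector of n outlyingness values (>= 0), with attributes
#'   `n_projections` (directions actually used, i.e. with nonzero MAD) and
#'   `seed`.
#' @details Directions along which the projected data have zero MAD carry no
#'   robust scale information and are skipped (this tolerates constant
#'   columns such as an all-nondetect channel); it is an error only if every
#'   direction is degenerate. In one dimension every direction is +/-1, so
#'   the estimate equals the exact univariate outlyingness
#'   `|x - median(x)| / (1.4826 * MAD(x))`.
#' @export
sde_outlyingness <- function(X, n_projections = 1000, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 3) abort_fmt("need at least 3 samples, got %d", n)
  if (p < 1) abort_fmt("need at least 1 variable")
  check_scalar_num(n_projections, "n_projections", lower = 1)
  if (any(!is.finite(X))) abort_fmt("X contains non-finite values")

  set.seed(stage_seed(seed, "sde-directions"))
  D <- matrix(stats::rnorm(n_projections * p), n_projections, p)
  D <- D / sqrt(rowSums(D^2))

  P <- X %*% t(D)                               # n x n_projections
  med <- apply(P, 2, stats::median)
  scl <- apply(P, 2, stats::mad)                # already includes 1.4826
  ok <- scl > 0
  if (!any(ok)) abort_fmt("all %d projections degenerate (zero MAD): data may be constant", n_projections)
  Z <- abs(sweep(P[, ok, drop = FALSE], 2, med[ok], `-`))
  Z <- sweep(Z, 2, scl[ok], `/`)
  out <- apply(Z, 1, max)
  attr(out, "n_projections") <- sum(ok)
  attr(out, "seed") <- seed
  out
}

#' Flag outliers from outlyingness values
#'
#' Strict inequality: a sample is flagged iff its value exceeds the cutoff
#' (default 3, the 3-sigma rule).
#'
#' @param values outlyingness values (finite).
#' @param cutoff critical value (default 3).
#' @param sample_id,class optional per-sample metadata carried into the
#'   report.
#' @return An `outlyingness_report`: data frame with `sample_id`, `class`,
#'   `outlyingness`, `flagged`, plus `cutoff`, `n_projections`, `seed`
#'   attributes.
#' @export
#' @examples
#' r <- flag_outliers(c(0.5, 3.0, 3.01))
#' r$flagged  # FALSE FALSE TRUE: strictly above 3 only
flag_outliers <- function(values, cutoff = 3, sample_id = NULL, class = NULL) {
  if (any(!is.finite(values))) abort_fmt("outlyingness values must be finite")
  rep <- data.frame(
    sample_id = sample_id %||% as.character(seq_along(values)),
    class = class %||% NA_character_,
    outlyingness = as.numeric(values),
    flagged = as.numeric(values) > cutoff,
    stringsAsFactors = FALSE
  )
  attr(rep, "cutoff") <- cutoff
  attr(rep, "n_projections") <- attr(values, "n_projections")
  attr(rep, "seed") <- attr(values, "seed")
  class(rep) <- c("outlyingness_report", "data.frame")
  rep
}

#' Per-class outlier screening
#'
#' Runs [sde_outlyingness()] independently within each husbandry class on
#' the rescaled representation (row-wise weight division followed by
#' autoscaling fitted on all samples, the exploratory-stage convention) and
#' removes flagged samples.
#'
#' @param table a [profile_table()]; both classes must have >= 3 samples.
#' @param n_projections random directions per class (default 1000).
#' @param cutoff critical value (default 3).
#' @param seed integer seed; each class gets a derived sub-seed.
#' @return `list(clean = <profile_table without flagged rows>,
#'   reports = <named list of outlyingness_report>,
#'   removed_ids = <character>)`.
#' @export
screen_by_class <- function(table, n_projections = 1000, cutoff = 3, seed = 1) {
  validate_profile_table(table)
  cls <- as.character(table$class)
  sizes <- table(factor(cls, levels = .class_levels))
  if (any(sizes < 3)) {
    abort_fmt("each class needs >= 3 samples for screening (got %s)",
              paste(sprintf("%s: %d", names(sizes), sizes), collapse = ", "))
  }
  M <- conc_matrix(rescale_rowwise(table))
  scaled <- autoscale_apply(M, autoscale_fit(M, subset_id = "all-samples"))
  reports <- lapply(.class_levels, function(cl) {
    idx <- which(cls == cl)
    vals <- sde_outlyingness(scaled[idx, , drop = FALSE],
                             n_projections = n_projections,
                             seed = stage_seed(seed, paste0("sde-", cl)))
    flag_outliers(vals, cutoff = cutoff,
                  sample_id = table$sample_id[idx], class = cl)
  })
  names(reports) <- .class_levels
  flagged_ids <- unlist(lapply(reports, function(r) r$sample_id[r$flagged]),
                        use.names = FALSE)
  clean <- table[!(table$sample_id %in% flagged_ids), , drop = FALSE]
  attr(clean, "panel") <- attr(table, "panel")
  attr(clean, "provenance") <- attr(table, "provenance")
  class(clean) <- class(table)
  list(clean = clean, reports = reports, removed_ids = flagged_ids)
}

#' Write an outlyingness report as CSV
#'
#' The per-sample table behind an outlier diagnostic curve
#' (sample, class, outlyingness, flag).
#'
#' @param report an `outlyingness_report` (or a named list of them).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_outlyingness_report <- function(report, path) {
  if (!inherits(report, "outlyingness_report") && is.list(report)) {
    report <- do.call(rbind, lapply(report, as.data.frame))
  }
  utils::write.csv(as.data.frame(report), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
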