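#' Derive a per-stage RNG seed from a global seed
#'
#' One global seed drives the whole pipeline; each stochastic stage (data
#' generation, outlier planting, projection directions, MCCV splits) gets its
#' own deterministic sub-seed so stages can be re-run independently without
#' sharing RNG state. The derivation is a fixed integer hash of the stage
#' name, kept strictly below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage label, e.g. `"generate"`, `"sde"`, `"mccv"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' stage_seed(1, "sde")
#' stage_seed(1, "mccv")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.character(stage), length(stage) == 1L, nzchar(stage))
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  # doubles are exact here: |seed| < 2^31, multipliers keep products < 2^53
  as.integer(((abs(seed) %% 2147483647) * 1009 + h * 9176) %% 2147483646)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero to a fixed number of decimals
#'
#' Presentation rounding for percentage metrics (round-half-up at 1 decimal),
#' as opposed to R's banker's rounding in `round()`.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# internal: stop with a message assembled sprintf-style
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# internal: check a scalar numeric
check_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_fmt("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    abort_fmt("`%s` = %g is outside [%g, %g]", name, x, lower, upper)
  }
  invisible(x)
}

# internal: coerce class labels to the +/-1 coding used by both classifiers.
# Accepts numeric +/-1 directly, otherwise characters/factors drawn from the
# two-class label set. Returns list(y = numeric, map = c(positive, negative)).
code_classes <- function(y, positive = "free-range", negative = "caged") {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) {
      abort_fmt("numeric class vector must contain only +1/-1")
    }
    return(list(y = as.numeric(y), map = c(positive = positive, negative = negative)))
  }
  y <- as.character(y)
  bad <- setdiff(unique(y), c(positive, negative))
  if (length(bad)) {
    abort_fmt("unknown class label(s): %s (expected '%s'/'%s')",
              paste(bad, collapse = ", "), positive, negative)
  }
  list(y = ifelse(y == positive, 1, -1),
       map = c(positive = positive, negative = negative))
}

# internal: decode +/-1 back to labels, zero assigned to the positive class
decode_classes <- function(score, map) {
  ifelse(score >= 0, map[["positive"]], map[["negative"]])
}
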