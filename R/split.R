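# Kennard-Stone maximin sample-set partitioning. Deterministic: the first
# two selections are the most distant pair; every later selection maximizes
# its minimum Euclidean distance to the already-selected set. Ties are
# broken toward the lowest index so results are identical across platforms.

#' Kennard-Stone selection
#'
#' @param X numeric n x p matrix (distances are Euclidean on these rows; in
#'   this workflow the autoscaled representation, so high-magnitude elements
#'   such as Ca do not dominate).
#' @param n_select number of samples to select, `2 <= n_select <= n`.
#' @return Integer vector of selected row indices, in selection order.
#' @export
#' @examples
#' kennard_stone(cbind(c(0, 1, 2, 10)), 3)  # 1, 4 (extremes) then 3
kennard_stone <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (any(is.na(X))) abort_fmt("X contains NA")
  check_scalar_num(n_select, "n_select", lower = 2, upper = n)
  n_select <- as.integer(n_select)

  D <- as.matrix(stats::dist(X))
  # initial pair: maximal distance; ties -> smallest (i, j) lexicographically
  mx <- max(D)
  hits <- which(D == mx, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  sel <- as.integer(hits[1, ])

  mind <- pmin(D[, sel[1]], D[, sel[2]])  # min distance of every row to the selected set
  mind[sel] <- -Inf
  while (length(sel) < n_select) {
    nxt <- as.integer(which.max(mind))    # which.max takes the lowest index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  unname(sel)
}

#' Per-class Kennard-Stone train/test split
#'
#' Runs [kennard_stone()] on each class's rows of the stated data
#' representation; selected rows form the training set (in selection
#' order), the remainder the test set.
#'
#' @param table a [profile_table()].
#' @param n_train training samples per class: single count or vector named
#'   by class (reference setting: 80 per class).
#' @param representation which matrix distances are measured on:
#'   `"autoscaled"` (weight-rescaled then autoscaled on all samples, the
#'   default), `"rowwise"` (weight-rescaled only) or `"raw"`.
#' @return A `split_result`: per class the ordered training ids/indices and
#'   test ids/indices, plus the representation and metric used.
#' @export
split_per_class <- function(table, n_train = c("free-range" = 80, "caged" = 80),
                            representation = c("autoscaled", "rowwise", "raw")) {
  validate_profile_table(table)
  representation <- match.arg(representation)
  if (length(n_train) == 1L && is.null(names(n_train))) {
    n_train <- stats::setNames(rep(n_train, 2), .class_levels)
  }
  if (!setequal(names(n_train), .class_levels)) abort_fmt("n_train must be named by class")

  M <- switch(representation,
    raw = conc_matrix(table),
    rowwise = conc_matrix(rescale_rowwise(table)),
    autoscaled = {
      M0 <- conc_matrix(rescale_rowwise(table))
      autoscale_apply(M0, autoscale_fit(M0, subset_id = "all-samples"))
    })

  cls <- as.character(table$class)
  per_class <- lapply(.class_levels, function(cl) {
    idx <- which(cls == cl)
    k <- n_train[[cl]]
    if (k > length(idx)) {
      abort_fmt("class '%s' has %d samples, cannot select %d for training",
                cl, length(idx), k)
    }
    sel_local <- kennard_stone(M[idx, , drop = FALSE], k)
    train <- idx[sel_local]
    test <- setdiff(idx, train)
    if (!length(test)) {
      warning(sprintf("class '%s': empty test set (all samples selected for training)", cl),
              call. = FALSE)
    }
    list(train_idx = train, test_idx = test,
         train_ids = table$sample_id[train], test_ids = table$sample_id[test])
  })
  names(per_class) <- .class_levels
  structure(list(classes = per_class,
                 metric = "euclidean", representation = representation,
                 n_train = vapply(per_class, function(z) length(z$train_idx), 1L),
                 n_test = vapply(per_class, function(z) length(z$test_idx), 1L)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> representation = %s\n", x$representation))
  for (cl in names(x$classes)) {
    cat(sprintf("  %-11s train %3d  test %3d\n", cl,
                length(x$classes[[cl]]$train_idx), length(x$classes[[cl]]$test_idx)))
  }
  invisible(x)
}

#' Pooled train/test indices from a split
#'
#' @param split a `split_result`.
#' @return `list(train = <int>, test = <int>)` over the whole table.
#' @export
split_indices <- function(split) {
  list(train = unlist(lapply(split$classes, `[[`, "train_idx"), use.names = FALSE),
       test = unlist(lapply(split$classes, `[[`, "test_idx"), use.names = FALSE))
}

#' Serialize a split result to JSON
#'
#' @param split a `split_result`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_split_result <- function(split, path) {
  jsonlite::write_json(
    list(metric = split$metric, representation = split$representation,
         classes = lapply(split$classes, function(z) {
           list(train_ids = z$train_ids, test_ids = z$test_ids)
         })),
    path, digits = NA, pretty = TRUE)
  invisible(path)
}
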