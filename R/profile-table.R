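# ProfileTable: the pipeline's universal data currency. A data.frame with
# one averaged record per eggshell sample: sample_id, class, producing area,
# digested sample weight (g), then the 16 element concentrations (ug/g) in
# panel column order. The element panel travels along as an attribute, and
# generator provenance (seed, config) as another.

.meta_cols <- c("sample_id", "class", "area", "weight_g")
.class_levels <- c("free-range", "caged")

#' Construct a profile table
#'
#' @param df data frame with columns `sample_id`, `class`, `area`,
#'   `weight_g` followed by one numeric column per panel element, in panel
#'   order.
#' @param panel an [element_panel()].
#' @param provenance optional list recorded as an attribute (e.g. generator
#'   seed and config).
#' @return A `profile_table` (data frame subclass).
#' @export
profile_table <- function(df, panel = element_panel(), provenance = NULL) {
  validate_profile_table(df, panel)
  attr(df, "panel") <- panel
  attr(df, "provenance") <- provenance
  class(df) <- c("profile_table", "data.frame")
  df
}

#' Validate a profile table against its panel
#'
#' Checks the schema (column names and order), label set, strictly positive
#' weights, and non-negative concentrations, reporting offending
#' rows/columns by name.
#'
#' @param df candidate data frame.
#' @param panel an [element_panel()].
#' @return `df`, invisibly.
#' @export
validate_profile_table <- function(df, panel = attr(df, "panel") %||% element_panel()) {
  missing_cols <- setdiff(c(.meta_cols, panel$element), names(df))
  if (length(missing_cols)) {
    abort_fmt("profile table is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  bad_lab <- setdiff(unique(as.character(df$class)), .class_levels)
  if (length(bad_lab)) {
    abort_fmt("unknown class label(s): %s (rows %s)",
              paste(bad_lab, collapse = ", "),
              paste(utils::head(which(df$class %in% bad_lab), 5), collapse = ", "))
  }
  for (el in panel$element) {
    if (!is.numeric(df[[el]])) abort_fmt("concentration column '%s' is not numeric", el)
    neg <- which(df[[el]] < 0)
    if (length(neg)) {
      abort_fmt("negative concentration in column '%s', row(s) %s",
                el, paste(utils::head(neg, 5), collapse = ", "))
    }
  }
  if (!is.numeric(df$weight_g) || any(!is.finite(df$weight_g)) || any(df$weight_g <= 0)) {
    abort_fmt("sample weights must be finite and strictly positive")
  }
  invisible(df)
}

#' Extract the n x 16 concentration matrix
#'
#' @param table a `profile_table`.
#' @return Numeric matrix, rows named by `sample_id`, columns by element.
#' @export
conc_matrix <- function(table) {
  panel <- attr(table, "panel") %||% element_panel()
  m <- as.matrix(as.data.frame(table)[, panel$element, drop = FALSE])
  rownames(m) <- table$sample_id
  m
}

#' Replace the concentration block of a profile table
#'
#' Internal-facing helper used by the preprocessing stages; keeps metadata
#' columns, panel and provenance intact.
#'
#' @param table a `profile_table`.
#' @param m replacement matrix with the same dimensions and column order.
#' @return The updated `profile_table`.
#' @export
set_conc_matrix <- function(table, m) {
  panel <- attr(table, "panel") %||% element_panel()
  stopifnot(nrow(m) == nrow(table), ncol(m) == length(panel$element))
  for (j in seq_along(panel$element)) table[[panel$element[j]]] <- m[, j]
  table
}

#' @export
print.profile_table <- function(x, ...) {
  tab <- table(as.character(x$class))
  cat(sprintf("<profile_table> %d samples x %d elements (%s)\n",
              nrow(x), nrow(attr(x, "panel") %||% element_panel()),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

#' Write a profile table to CSV (with JSON provenance sidecar)
#'
#' Plain UTF-8 CSV, comma separated, '.' decimal, header mandatory:
#' `sample_id,class,area,weight_g,Zn,...,K`. If the table carries
#' provenance, it is written next to the CSV as `<path>.provenance.json`.
#'
#' @param table a `profile_table`.
#' @param path output CSV path.
#' @param provenance_path optional explicit sidecar path; `NULL` derives it
#'   from `path`, `NA` suppresses the sidecar.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(table, path, provenance_path = NULL) {
  validate_profile_table(table)
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  prov <- attr(table, "provenance")
  if (!is.null(prov) && !isTRUE(is.na(provenance_path))) {
    pp <- provenance_path %||% paste0(path, ".provenance.json")
    jsonlite::write_json(prov, pp, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a profile table from CSV
#'
#' Inverse of [write_profiles()]. Values round-trip losslessly at up to ~10
#' significant digits. Schema violations (missing columns, non-numeric
#' concentrations, unknown class labels) are reported with row/column
#' context.
#'
#' @param path CSV path.
#' @param panel panel to validate against (default: the reference panel).
#' @return A `profile_table`.
#' @export
read_profiles <- function(path, panel = element_panel()) {
  if (!file.exists(path)) abort_fmt("profile CSV not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(c(.meta_cols, panel$element), names(df))
  if (length(missing_cols)) {
    abort_fmt("profile CSV '%s' is missing column(s): %s",
              path, paste(missing_cols, collapse = ", "))
  }
  for (col in c("weight_g", panel$element)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad)) {
      abort_fmt("non-numeric value in column '%s', row(s) %s of %s",
                col, paste(utils::head(bad, 5), collapse = ", "), path)
    }
    df[[col]] <- v
  }
  prov_path <- paste0(path, ".provenance.json")
  prov <- if (file.exists(prov_path)) jsonlite::read_json(prov_path, simplifyVector = TRUE)
  profile_table(df, panel = panel, provenance = prov)
}
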