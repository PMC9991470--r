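# Pipeline orchestration: one declarative config drives
# read/generate -> weight rescale -> per-class SDE screening -> per-class
# Kennard-Stone split -> train-set autoscaling -> MCCV parameter selection
# -> final fits -> test-set evaluation, with every intermediate artifact
# written to the run directory and summarized in a machine-readable report.

#' Build a pipeline configuration
#'
#' Defaults equal the reference workflow settings: 1000 projections at
#' cutoff 3 for outlier screening, 80 training samples per class, 100 MCCV
#' splits at 70/30, PLS-DA LV grid 1..10 and the (sigma2, gamma) lattice
#' covering (700, 5).
#'
#' @param input path to a profile CSV, or `NULL` to generate synthetic data.
#' @param n_per_class generator class sizes (ignored when `input` given).
#' @param plant_k,plant_displacement planted gross outliers per class (for
#'   screening-recovery studies); `plant_k = 0` plants none.
#' @param n_projections,cutoff SDE screening settings.
#' @param n_train Kennard-Stone training samples per class.
#' @param representation distance representation for the split
#'   (see [split_per_class()]).
#' @param models character vector of model families to tune and evaluate
#'   (subset of `"plsda"`, `"lssvm"`; empty = preprocessing only).
#' @param lv_grid,lssvm_grid tuning grids.
#' @param n_splits,train_frac MCCV settings.
#' @param seed global seed; all stage seeds derive from it.
#' @param out_dir artifact directory, or `NULL` to keep everything in
#'   memory.
#' @param verbose log one line per stage to stderr.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL,
                            n_per_class = c("free-range" = 127, "caged" = 122),
                            plant_k = c("free-range" = 0, "caged" = 0),
                            plant_displacement = 10,
                            n_projections = 1000, cutoff = 3,
                            n_train = c("free-range" = 80, "caged" = 80),
                            representation = "autoscaled",
                            models = c("plsda", "lssvm"),
                            lv_grid = default_lv_grid(),
                            lssvm_grid = default_lssvm_grid(),
                            n_splits = 100, train_frac = 0.7,
                            seed = 20190101,
                            out_dir = NULL, verbose = FALSE) {
  bad <- setdiff(models, c("plsda", "lssvm"))
  if (length(bad)) abort_fmt("unknown model family: %s", paste(bad, collapse = ", "))
  # NULL round-trips through JSON as an empty container; normalize back
  if (length(input) == 0) input <- NULL
  if (length(out_dir) == 0) out_dir <- NULL
  models <- as.character(unlist(models))
  structure(list(input = input, n_per_class = n_per_class,
                 plant_k = plant_k, plant_displacement = plant_displacement,
                 n_projections = n_projections, cutoff = cutoff,
                 n_train = n_train, representation = representation,
                 models = models, lv_grid = lv_grid, lssvm_grid = lssvm_grid,
                 n_splits = n_splits, train_frac = train_frac,
                 seed = seed, out_dir = out_dir, verbose = verbose),
            class = "pipeline_config")
}

#' Read / write a pipeline config (JSON)
#'
#' The serialized form round-trips losslessly through
#' [write_pipeline_config()] and is validated on read.
#'
#' @param path JSON file path.
#' @return A `pipeline_config` / `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_fmt("config not found: %s", path)
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- pipeline_config()
  unknown <- setdiff(names(o), names(defaults))
  if (length(unknown)) abort_fmt("unknown config field(s): %s", paste(unknown, collapse = ", "))
  for (nm in names(o)) {
    v <- o[[nm]]
    if (nm %in% c("n_per_class", "plant_k", "n_train")) v <- unlist(v)
    if (nm == "lssvm_grid") v <- as.data.frame(v)
    defaults[[nm]] <- v
  }
  do.call(pipeline_config, unclass(defaults))
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  obj <- unclass(config)
  for (nm in c("n_per_class", "plant_k", "n_train")) obj[[nm]] <- as.list(obj[[nm]])
  jsonlite::write_json(obj, path, digits = NA, pretty = TRUE, auto_unbox = TRUE)
  invisible(path)
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[eggchem] ", fmt), ...))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort_fmt("stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full authentication pipeline
#'
#' Executes every stage from a [pipeline_config()] and returns a run
#' report. All randomness derives from `config$seed`; a rerun with an
#' identical config reproduces the report bit-for-bit (file timestamps
#' aside). When `out_dir` is set, every intermediate artifact (profile CSV,
#' outlyingness report, split JSON, MCCV surfaces, fitted models, report
#' JSON) is written there and listed in the report's manifest with MD5
#' checksums.
#'
#' @param config a [pipeline_config()] (or path to its JSON form).
#' @return A `run_report` list; see Details.
#' @details Report components: `panel`, `counts` (per-stage sample
#'   bookkeeping), `outliers` (per-class reports), `split`, and per model
#'   family the selected parameters, MCCV surface, test-set confusion
#'   counts and metrics. Scaling for classifier training/testing is fit on
#'   the training rows only.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  artifact <- function(name) if (is.null(out_dir)) NULL else file.path(out_dir, name)
  manifest <- character(0)
  keep <- function(path) { if (!is.null(path)) manifest <<- c(manifest, path); invisible(path) }

  # -- acquire data -----------------------------------------------------
  truth <- NULL
  table <- with_stage("input", {
    if (!is.null(config$input)) {
      read_profiles(config$input)
    } else {
      generate_profiles(cfg = generator_config(
        n_per_class = config$n_per_class, seed = config$seed))
    }
  })
  log_stage(config$verbose, "input: %d samples (%s)", nrow(table),
            paste(sprintf("%s: %d", names(table(table$class)), table(table$class)), collapse = ", "))
  if (sum(config$plant_k) > 0) {
    planted <- with_stage("plant-outliers", plant_outliers(
      table, k = config$plant_k, displacement = config$plant_displacement,
      seed = stage_seed(config$seed, "plant")))
    table <- planted$table
    truth <- planted$ids
    log_stage(config$verbose, "planted %d outlier(s): %s", length(truth),
              paste(truth, collapse = ", "))
  }
  if (!is.null(artifact("profiles.csv"))) keep(write_profiles(table, artifact("profiles.csv")))

  # -- screening --------------------------------------------------------
  screened <- with_stage("sde-screen", screen_by_class(
    table, n_projections = config$n_projections, cutoff = config$cutoff,
    seed = stage_seed(config$seed, "sde")))
  clean <- screened$clean
  log_stage(config$verbose, "screening removed %d sample(s), %d remain",
            length(screened$removed_ids), nrow(clean))
  if (!is.null(artifact("outlyingness.csv"))) {
    keep(write_outlyingness_report(screened$reports, artifact("outlyingness.csv")))
  }

  # -- split ------------------------------------------------------------
  split <- with_stage("kennard-stone", split_per_class(
    clean, n_train = config$n_train, representation = config$representation))
  idx <- split_indices(split)
  log_stage(config$verbose, "split: train %d, test %d", length(idx$train), length(idx$test))
  if (!is.null(artifact("split.json"))) keep(write_split_result(split, artifact("split.json")))

  # -- modelling --------------------------------------------------------
  M <- conc_matrix(rescale_rowwise(clean))
  y <- as.character(clean$class)
  model_reports <- list()
  scaling <- NULL
  if (length(config$models)) {
    scaling <- with_stage("autoscale-train", autoscale_fit(
      M, subset = idx$train, subset_id = "training-set"))
    Xtr <- autoscale_apply(M[idx$train, , drop = FALSE], scaling)
    Xte <- autoscale_apply(M[idx$test, , drop = FALSE], scaling)
    ytr <- y[idx$train]; yte <- y[idx$test]
    if (!is.null(artifact("scaling.json"))) keep(write_scaling_params(scaling, artifact("scaling.json")))

    for (family in config$models) {
      grid <- if (family == "plsda") config$lv_grid else config$lssvm_grid
      tuned <- with_stage(paste0("mccv-", family), grid_search(
        family, M[idx$train, , drop = FALSE], ytr, grid = grid,
        n_splits = config$n_splits, train_frac = config$train_frac,
        seed = stage_seed(config$seed, paste0("mccv-", family))))
      model <- with_stage(paste0("fit-", family), {
        if (family == "plsda") plsda_fit(Xtr, ytr, tuned$selected$lv)
        else lssvm_fit(Xtr, ytr, tuned$selected$sigma2, tuned$selected$gamma)
      })
      pred <- with_stage(paste0("evaluate-", family), {
        if (family == "plsda") plsda_predict(model, Xte) else lssvm_predict(model, Xte)
      })
      counts <- confusion(yte, pred$class)
      metr <- class_metrics(counts)
      log_stage(config$verbose, "%s: MCCVER %.4f at %s; test accuracy %.1f%%",
                family, tuned$selected$mccver,
                paste(names(tuned$selected)[-ncol(tuned$selected)],
                      unlist(tuned$selected)[-ncol(tuned$selected)],
                      sep = "=", collapse = ", "),
                metr$percent["accuracy"])
      if (!is.null(out_dir)) {
        keep(write_mccv_grid(tuned, artifact(sprintf("mccv_%s.csv", family))))
        if (family == "plsda") keep(write_plsda_model(model, artifact("model_plsda.json")))
        else keep(write_lssvm_model(model, artifact("model_lssvm.json")))
      }
      model_reports[[family]] <- list(
        selected = as.list(tuned$selected),
        mccv = list(n_splits = tuned$n_splits, train_frac = tuned$train_frac,
                    seed = tuned$seed, convention = tuned$convention),
        confusion = unclass(counts),
        metrics = list(fractions = list(sensitivity = metr$sensitivity,
                                        specificity = metr$specificity,
                                        accuracy = metr$accuracy),
                       percent = as.list(metr$percent)))
    }
  }

  report <- structure(list(
    config = unclass(config),
    seed = config$seed,
    panel = as.data.frame(attr(clean, "panel") %||% element_panel()),
    counts = list(input = nrow(table),
                  per_class_input = as.list(table(as.character(table$class))),
                  removed = length(screened$removed_ids),
                  post_screen = nrow(clean),
                  per_class_post_screen = as.list(table(as.character(clean$class))),
                  train = length(idx$train), test = length(idx$test),
                  test_per_class = as.list(split$n_test)),
    planted_ids = truth,
    removed_ids = screened$removed_ids,
    outliers = lapply(screened$reports, function(r) {
      list(cutoff = attr(r, "cutoff"), n_projections = attr(r, "n_projections"),
           flagged = r$sample_id[r$flagged])
    }),
    split = lapply(split$classes, function(z) list(train_ids = z$train_ids,
                                                   test_ids = z$test_ids)),
    scaling_subset = if (is.null(scaling)) NULL else scaling$subset_id,
    models = model_reports),
    class = "run_report")

  if (!is.null(out_dir)) {
    report$manifest <- data.frame(
      file = basename(manifest),
      md5 = as.character(tools::md5sum(manifest)),
      stringsAsFactors = FALSE)
    report_path <- artifact("report.json")
    jsonlite::write_json(unclass(report), report_path, digits = NA,
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %s: %d -> screen %d -> train %d / test %d\n",
              format(x$seed), x$counts$input, x$counts$post_screen,
              x$counts$train, x$counts$test))
  for (family in names(x$models)) {
    m <- x$models[[family]]
    cat(sprintf("  %-7s %s | accuracy %.1f%% sensitivity %.1f%% specificity %.1f%%\n",
                family,
                paste(names(m$selected), unlist(m$selected), sep = "=", collapse = " "),
                m$metrics$percent$accuracy, m$metrics$percent$sensitivity,
                m$metrics$percent$specificity))
  }
  invisible(x)
}
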