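# Experiment orchestration: expand a (mechanism x alpha x seed) grid over
# one dataset + hierarchy, train, evaluate severity/accuracy, aggregate.

#' Evaluate a trained model on a test set
#'
#' @param model a trained `cascade_model`.
#' @param X,y test inputs and integer leaf targets.
#' @param hierarchy the semantic `label_hierarchy` to score against (for
#'   RHCL this is the original hierarchy, not the randomised one).
#' @param mode prediction source for the per-level matrix (see
#'   [predict_levels()]); project-leaf compares all mechanisms on
#'   identical footing.
#' @return list with `leaf_accuracy`, `severity` (a `severity_report`),
#'   `per_level_accuracy` and `confusion` (hierarchy-ordered).
#' @export
evaluate_model <- function(model, X, y, hierarchy,
                           mode = c("project-leaf", "stage-heads")) {
  mode <- match.arg(mode)
  y <- as.integer(y)
  pred <- predict_levels(model, hierarchy, X, mode = mode)
  truth <- build_stage_targets(hierarchy, y)
  leaf <- predict_leaf(model, X)$leaf
  list(leaf_accuracy = mean(leaf == y),
       severity = classifier_severity(pred, truth),
       per_level_accuracy = per_level_accuracy(pred, truth),
       confusion = suppressWarnings(
         hierarchy_ordered_confusion(leaf, y, hierarchy)))
}

#' Run a full experiment grid
#'
#' For every (mechanism, alpha, seed) cell: train on the train split,
#' evaluate severity and accuracy on the test split against the semantic
#' hierarchy, and aggregate mean and standard deviation across seeds.
#'
#' @param config a named list (or path to a YAML file) with fields:
#'   `preset` (fixture preset name) or `data` (list with `train`, `test`,
#'   `hierarchy`, `embeddings` paths); `mechanisms` (character vector);
#'   `alphas` (numeric vector, default 0); `seeds` (integer vector);
#'   `model` (overrides for [cascade_config()]: `widths`, `u`, `epochs`,
#'   `lr`, `batch_size`); `evaluation_mode`; `out_dir` (optional: write
#'   `report.json` and `report.csv` there).
#' @return a `run_report` list with one record per cell (`runs`),
#'   per-group aggregates (`aggregate`), the config echo, a data
#'   fingerprint and wall time.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  t0 <- proc.time()[["elapsed"]]
  mechanisms <- toupper(config$mechanisms %||% "NSCL")
  alphas <- config$alphas %||% 0
  seeds <- as.integer(config$seeds %||% 1L)
  mode <- config$evaluation_mode %||% "project-leaf"
  mc <- config$model %||% list()

  if (!is.null(config$preset)) {
    work <- file.path(tempfile("nscl_fixture_"))
    make_fixture_bundle(config$preset, seed = seeds[[1L]], out_dir = work)
    data_paths <- list(train = file.path(work, "train.csv"),
                       test = file.path(work, "test.csv"),
                       hierarchy = file.path(work, "hierarchy.json"),
                       embeddings = file.path(work, "embeddings.txt"))
  } else if (!is.null(config$data)) {
    data_paths <- config$data
  } else stop("config needs either 'preset' or 'data' paths")

  hierarchy <- read_hierarchy_json(data_paths$hierarchy)
  train <- read_dataset_csv(data_paths$train, leaves = hierarchy$leaves)
  test <- read_dataset_csv(data_paths$test, leaves = hierarchy$leaves)
  embeddings <- if (!is.null(data_paths$embeddings)) {
    src <- read_word2vec(data_paths$embeddings)
    src[hierarchy$leaves, , drop = FALSE]
  }
  fingerprint <- rlang::hash(list(train$X, train$y, hierarchy$levels))

  runs <- list()
  errors <- list()
  for (mech in mechanisms) for (alpha in alphas) for (seed in seeds) {
    cell <- sprintf("%s_a%g_s%d", mech, alpha, seed)
    rec <- tryCatch({
      cfg <- cascade_config(
        mechanism = mech,
        widths = mc$widths %||% 32L,
        u = if (!is.null(embeddings)) ncol(embeddings) else mc$u %||% 16L,
        epochs = mc$epochs %||% 10L, lr = mc$lr %||% 1e-3,
        batch_size = mc$batch_size %||% 64L, alpha = alpha,
        depth = mc$depth %||% hierarchy$L, seed = seed)
      fit <- train_cascade(train$X, train$y, cfg, hierarchy = hierarchy,
                           embeddings = embeddings)
      ev <- evaluate_model(fit$model, test$X, test$y, hierarchy, mode = mode)
      list(mechanism = mech, alpha = alpha, seed = seed,
           leaf_accuracy = ev$leaf_accuracy,
           severity = ev$severity$mean,
           per_level_accuracy = ev$per_level_accuracy)
    }, error = function(e) {
      errors[[cell]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(rec)) runs[[cell]] <- rec
  }

  agg <- list()
  for (mech in mechanisms) for (alpha in alphas) {
    sel <- Filter(function(r) r$mechanism == mech && r$alpha == alpha, runs)
    if (!length(sel)) next
    sev <- vapply(sel, `[[`, numeric(1L), "severity")
    acc <- vapply(sel, `[[`, numeric(1L), "leaf_accuracy")
    agg[[sprintf("%s_a%g", mech, alpha)]] <- list(
      mechanism = mech, alpha = alpha, n_seeds = length(sel),
      severity_mean = mean(sev),
      severity_sd = if (length(sev) > 1L) stats::sd(sev) else 0,
      accuracy_mean = mean(acc),
      accuracy_sd = if (length(acc) > 1L) stats::sd(acc) else 0)
  }

  report <- structure(list(
    runs = runs, aggregate = agg, errors = errors,
    config = config, data_fingerprint = fingerprint,
    wall_time_s = proc.time()[["elapsed"]] - t0,
    versions = list(nscl = as.character(utils::packageVersion("nscl")),
                    r = paste(R.version$major, R.version$minor, sep = "."))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' Write a run report as JSON and CSV
#'
#' @param report a `run_report`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (length(report$runs)) {
    df <- do.call(rbind, lapply(report$runs, function(r)
      data.frame(mechanism = r$mechanism, alpha = r$alpha, seed = r$seed,
                 leaf_accuracy = r$leaf_accuracy, severity = r$severity)))
    utils::write.csv(df, file.path(out_dir, "report.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}

#' Validate a run report against the bundled schema
#'
#' A minimal structural check (required fields and types) against
#' `inst/extdata/report-schema.json`.
#'
#' @param report a `run_report` (or a list parsed from `report.json`).
#' @return TRUE invisibly, or an error naming the first violation.
#' @export
validate_run_report <- function(report) {
  schema <- jsonlite::fromJSON(
    system.file("extdata", "report-schema.json", package = "nscl"),
    simplifyVector = FALSE)
  check_against <- function(obj, spec, where) {
    for (field in names(spec$required)) {
      if (is.null(obj[[field]]))
        stop("report invalid: missing '", field, "' at ", where)
      type <- spec$required[[field]]
      ok <- switch(type,
        number = is.numeric(obj[[field]]),
        string = is.character(obj[[field]]),
        list = is.list(obj[[field]]),
        TRUE)
      if (!ok) stop("report invalid: '", field, "' at ", where,
                    " should be a ", type)
    }
  }
  check_against(report, schema$report, "top level")
  for (nm in names(report$runs))
    check_against(report$runs[[nm]], schema$run, nm)
  for (nm in names(report$aggregate))
    check_against(report$aggregate[[nm]], schema$aggregate, nm)
  invisible(TRUE)
}

#' Rank mechanisms by severity across reports
#'
#' Pools the aggregate rows of one or more reports over identical data,
#' sorts by mean severity ascending and flags pairs whose ±1 standard
#' error intervals do not overlap with the next-ranked row.
#'
#' @param reports a `run_report` or list of them (same data fingerprint).
#' @return data.frame sorted by `severity_mean` with columns `mechanism`,
#'   `alpha`, `severity_mean`, `severity_se`, `accuracy_mean`,
#'   `distinct_from_next` (logical).
#' @export
compare_mechanisms <- function(reports) {
  if (inherits(reports, "run_report")) reports <- list(reports)
  fps <- vapply(reports, `[[`, character(1L), "data_fingerprint")
  if (length(unique(fps)) != 1L)
    stop("reports were computed on different data (fingerprint mismatch)")
  rows <- do.call(rbind, lapply(reports, function(rep)
    do.call(rbind, lapply(rep$aggregate, function(a)
      data.frame(mechanism = a$mechanism, alpha = a$alpha,
                 severity_mean = a$severity_mean,
                 severity_se = a$severity_sd / sqrt(max(1L, a$n_seeds)),
                 accuracy_mean = a$accuracy_mean)))))
  if (is.null(rows) || !nrow(rows)) stop("no aggregate rows to compare")
  ord <- order(rows$severity_mean)
  rows <- rows[ord, , drop = FALSE]
  n <- nrow(rows)
  rows$distinct_from_next <- c(
    if (n > 1L)
      (rows$severity_mean[-n] + rows$severity_se[-n]) <
        (rows$severity_mean[-1L] - rows$severity_se[-1L])
    else logical(0),
    NA)
  rownames(rows) <- NULL
  rows
}
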