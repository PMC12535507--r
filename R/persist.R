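#' Save a trained cascade model to a directory
#'
#' Writes the parameter store (`model.rds`) next to a JSON manifest
#' echoing stages, head widths, per-block checksums and the training
#' report, so a run is inspectable without loading the parameters.
#'
#' @param model a `cascade_model`.
#' @param dir output directory (created if missing).
#' @param report optional training report (from [train_cascade()]).
#' @return `dir`, invisibly.
#' @export
save_cascade_model <- function(model, dir, report = NULL) {
  stopifnot(inherits(model, "cascade_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  manifest <- list(
    input_dim = model$input_dim, u = model$u,
    input_shape = model$input_shape, class_labels = model$class_labels,
    n_blocks = length(model$blocks), n_heads = length(model$heads),
    head_widths = vapply(model$heads, `[[`, integer(1L), "k"),
    checksums = as.list(block_checksums(model)),
    report = if (!is.null(report))
      report[setdiff(names(report), "trained_hierarchy")]
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(report$trained_hierarchy))
    write_hierarchy_json(report$trained_hierarchy,
                         file.path(dir, "trained_hierarchy.json"))
  invisible(dir)
}

#' Load a cascade model saved by [save_cascade_model()]
#'
#' @param dir model directory.
#' @return the `cascade_model`.
#' @export
load_cascade_model <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) stop("no model.rds under ", dir)
  model <- readRDS(path)
  if (!inherits(model, "cascade_model")) stop("not a cascade model: ", path)
  model
}
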