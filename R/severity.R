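#' Per-level mismatch indicators
#'
#' Entry `(i, l)` is 1 when sample i's prediction differs from the truth
#' at level l, before any propagation.
#'
#' @param predictions integer matrix (m x L) of predicted cluster ids.
#' @param truths integer matrix (m x L) of true cluster ids.
#' @return binary integer matrix (m x L).
#' @export
per_level_mismatch <- function(predictions, truths) {
  predictions <- as.matrix(predictions); truths <- as.matrix(truths)
  if (!all(dim(predictions) == dim(truths)))
    stop("prediction and truth matrices must have matching shapes")
  matrix(as.integer(predictions != truths), nrow(predictions))
}

#' Severity of one sample from its mismatch pattern
#'
#' With propagation (the default), an error at any level forces every
#' deeper level to count as an error — a mistake at a coarse level cannot
#' be repaired downstream — so severity is `(L - first_error + 1) / L`, or
#' 0 when every level matches. A higher value means the first mistake
#' happened at a broader, more consequential category. Without propagation
#' the raw mismatch fraction `sum(S_l) / L` is returned (diagnostic only).
#'
#' @param mismatch binary vector of length L (1 = mismatch at that level).
#' @param propagate logical; propagate errors downward (default TRUE).
#' @return scalar in `[0, 1]`.
#' @export
sample_severity <- function(mismatch, propagate = TRUE) {
  mismatch <- as.integer(mismatch)
  L <- length(mismatch)
  if (L == 0L) stop("mismatch vector must have at least one level")
  if (any(!mismatch %in% c(0L, 1L))) stop("mismatch entries must be 0 or 1")
  if (propagate) {
    first <- which(mismatch == 1L)
    if (!length(first)) return(0)
    (L - first[[1L]] + 1) / L
  } else {
    sum(mismatch) / L
  }
}

#' Severity report for a classifier
#'
#' Mean severity over samples (the classifier expectation), per-sample
#' severities and per-level mismatch rates.
#'
#' @inheritParams per_level_mismatch
#' @param propagate propagate errors to deeper levels (default TRUE).
#' @return a `severity_report`: list with `per_sample`, `mean`,
#'   `per_level_mismatch_rates`, `m`, `L`, `propagate`.
#' @export
classifier_severity <- function(predictions, truths, propagate = TRUE) {
  M <- per_level_mismatch(predictions, truths)
  if (nrow(M) < 1L) stop("need at least one sample")
  per_sample <- apply(M, 1L, sample_severity, propagate = propagate)
  structure(list(per_sample = unname(per_sample), mean = mean(per_sample),
                 per_level_mismatch_rates = unname(colMeans(M)),
                 m = nrow(M), L = ncol(M), propagate = propagate),
            class = "severity_report")
}

#' @export
print.severity_report <- function(x, ...) {
  cat("severity report:", x$m, "samples,", x$L, "levels\n")
  cat("  mean severity:", format(x$mean, digits = 4), "\n")
  cat("  per-level mismatch rates:",
      paste(format(x$per_level_mismatch_rates, digits = 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-level accuracy
#'
#' @inheritParams per_level_mismatch
#' @return numeric vector of length L: `1 - mean mismatch` per level.
#' @export
per_level_accuracy <- function(predictions, truths) {
  1 - colMeans(per_level_mismatch(predictions, truths))
}

#' Hierarchy-ordered confusion matrix with log-intensity transform
#'
#' Rows (truth) and columns (prediction) are ordered by a depth-first
#' traversal of the hierarchy (children in cluster-id order), so leaves
#' sharing coarse clusters are adjacent and within-group confusions form
#' diagonal blocks. The diagonal (correct classifications) is zeroed and
#' the error counts are transformed to
#' `-log((count + pseudocount) / (total_errors + pseudocount * cells))`
#' over the off-diagonal cells (Haldane–Anscombe-style pseudocount for
#' zero cells).
#'
#' @param leaf_predictions integer vector of predicted leaf indices.
#' @param leaf_truths integer vector of true leaf indices.
#' @param hierarchy a `label_hierarchy`.
#' @param pseudocount added to every cell before the log (default 0.5).
#' @return list with `counts` (zero-diagonal matrix in hierarchy order),
#'   `intensity` (same shape, `NA` diagonal; `NULL` with a warning when
#'   there are no errors), `leaf_order`, `supergroup` (level-1 id per
#'   ordered leaf) and `within_group_error_fraction`.
#' @export
hierarchy_ordered_confusion <- function(leaf_predictions, leaf_truths,
                                        hierarchy, pseudocount = 0.5) {
  validate_label_hierarchy(hierarchy)
  n <- length(hierarchy$leaves)
  leaf_predictions <- as.integer(leaf_predictions)
  leaf_truths <- as.integer(leaf_truths)
  if (any(c(leaf_predictions, leaf_truths) < 1L) ||
      any(c(leaf_predictions, leaf_truths) > n))
    stop("leaf index outside 1..", n)
  keys <- c(lapply(seq_len(hierarchy$L),
                   function(l) unname(hierarchy$levels[[l]])),
            list(seq_len(n)))
  ord <- do.call(order, keys)
  counts <- matrix(0L, n, n,
                   dimnames = list(truth = hierarchy$leaves[ord],
                                   prediction = hierarchy$leaves[ord]))
  pos <- match(seq_len(n), ord)
  for (i in seq_along(leaf_truths)) {
    counts[pos[leaf_truths[i]], pos[leaf_predictions[i]]] <-
      counts[pos[leaf_truths[i]], pos[leaf_predictions[i]]] + 1L
  }
  diag(counts) <- 0L
  total_errors <- sum(counts)
  super <- unname(hierarchy$levels[[1L]][ord])
  same_super <- outer(super, super, "==")
  within_frac <- if (total_errors > 0)
    sum(counts[same_super]) / total_errors else NA_real_
  intensity <- NULL
  if (total_errors == 0) {
    warning("no misclassifications: intensity matrix is undefined")
  } else {
    cells <- n * (n - 1L)
    intensity <- -log((counts + pseudocount) /
                        (total_errors + pseudocount * cells))
    diag(intensity) <- NA_real_
  }
  list(counts = counts, intensity = intensity,
       leaf_order = hierarchy$leaves[ord], supergroup = super,
       within_group_error_fraction = within_frac)
}
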