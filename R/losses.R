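#' Cosine alignment (embedding regression) loss
#'
#' Mean over samples of `1 - cosine_similarity(target_i, latent_i)`:
#' zero when every latent representation points along its target word
#' embedding, two under perfect anti-alignment. Pulls the network's latent
#' space toward the semantic geometry of the class labels.
#'
#' @param latent numeric matrix (m x u) of latent representations.
#' @param targets numeric matrix (m x u) of per-sample target embeddings.
#' @return scalar in `[0, 2]`.
#' @export
cosine_alignment_loss <- function(latent, targets) {
  latent <- as.matrix(latent); targets <- as.matrix(targets)
  if (!all(dim(latent) == dim(targets)))
    stop("latent and target matrices must have matching dimensions")
  if (!all(is.finite(latent)) || !all(is.finite(targets)))
    stop("non-finite entries in latent or target matrix")
  nl <- row_norms(latent); nt <- row_norms(targets)
  bad <- which(nl == 0 | nt == 0)
  if (length(bad))
    stop("zero-norm vector at row(s): ", paste(bad, collapse = ", "))
  cosine <- rowSums(latent * targets) / (nl * nt)
  mean(1 - cosine)
}

#' Per-class weights from training counts
#'
#' `weight_c = N / (K * n_c)` where `N` is the total sample count and `K`
#' the number of classes: balanced counts give all-ones; rare classes are
#' up-weighted in proportion to their scarcity.
#'
#' @param counts positive integer vector of per-class sample counts.
#' @return numeric vector of positive weights, same length as `counts`.
#' @export
class_weights_from_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L || any(!is.finite(counts)) ||
      any(counts != round(counts)))
    stop("counts must be integers")
  if (any(counts <= 0))
    stop("class absent from the training split (zero count at index ",
         paste(which(counts <= 0), collapse = ", "), ")")
  sum(counts) / (length(counts) * counts)
}

#' Class-weighted categorical cross-entropy
#'
#' Weighted mean of `-log(score at the true class)`; each sample is
#' weighted by its true class's weight and the total is normalised by the
#' sum of applied weights, keeping the loss scale comparable across
#' imbalance regimes. Zero scores at a true class are clamped at 1e-12
#' with a warning.
#'
#' @param scores numeric matrix (m x K), rows on the probability simplex.
#' @param targets integer vector of true class indices in `1..K`.
#' @param weights positive per-class weights (default: unit weights).
#' @return non-negative scalar.
#' @export
weighted_cross_entropy <- function(scores, targets,
                                   weights = rep(1, ncol(scores))) {
  scores <- as.matrix(scores)
  m <- nrow(scores); K <- ncol(scores)
  targets <- as.integer(targets)
  if (length(targets) != m) stop("one target per score row required")
  if (any(targets < 1L | targets > K)) stop("target index out of range 1..", K)
  if (length(weights) != K || any(weights <= 0))
    stop("weights must be positive, one per class")
  p <- scores[cbind(seq_len(m), targets)]
  if (any(p <= 0)) {
    warning("score of 0 at a true class; clamped at 1e-12")
    p <- pmax(p, 1e-12)
  }
  w <- weights[targets]
  sum(w * -log(p)) / sum(w)
}

#' Resolve the regression/classification weighting schedule
#'
#' For regression weight `alpha < 1` the classification weight is
#' `beta = 1 - alpha` (a convex combination); for `alpha >= 1`, `beta` is
#' fixed at 1 and `alpha` alone scales the regression term.
#'
#' @param alpha non-negative regression weight (explored in `[0, 7]`).
#' @return a `loss_weights` object with fields `alpha`, `beta`.
#' @export
resolve_weight_schedule <- function(alpha) {
  assert_scalar_number(alpha, "alpha")
  if (alpha < 0) stop("alpha must be non-negative")
  beta <- if (alpha < 1) 1 - alpha else 1
  structure(list(alpha = alpha, beta = beta), class = "loss_weights")
}

#' Combine regression and classification losses
#'
#' `alpha * regression + beta * classification`.
#'
#' @param weights a `loss_weights` object (see [resolve_weight_schedule()]).
#' @param regression non-negative finite scalar.
#' @param classification non-negative finite scalar.
#' @return scalar combined loss.
#' @export
combined_loss <- function(weights, regression, classification) {
  if (!inherits(weights, "loss_weights"))
    weights <- resolve_weight_schedule(weights)
  assert_scalar_number(regression, "regression")
  assert_scalar_number(classification, "classification")
  if (regression < 0 || classification < 0)
    stop("loss terms must be non-negative")
  weights$alpha * regression + weights$beta * classification
}
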