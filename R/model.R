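# Internal network machinery for the cascade: affine feature blocks with
# ReLU, per-stage output blocks (projection to the embedding dimension u,
# ReLU, affine head, softmax), manual backpropagation and Adam updates.
# Written from scratch: staged growth with freeze/fine-tune scopes is the
# method itself, and no deep-learning framework ships with the R stack.

init_affine <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}

#' Create an empty cascade model
#'
#' @param input_dim number of input features (images are flattened).
#' @param u embedding dimension; every stage's projection maps to `u` units
#'   so the latent space can be regressed onto label embeddings.
#' @param input_shape optional `c(height, width)` or `c(height, width,
#'   channels)` of raster inputs, kept so saliency maps can be reshaped.
#' @param class_labels optional character vector mapping leaf index to
#'   label, recorded for reports.
#' @return an object of class `cascade_model` with no blocks yet.
#' @export
new_cascade_model <- function(input_dim, u, input_shape = NULL,
                              class_labels = NULL) {
  stopifnot(input_dim >= 1L, u >= 1L)
  if (!is.null(input_shape) && prod(input_shape) != input_dim)
    stop("input_shape is inconsistent with input_dim")
  structure(list(input_dim = as.integer(input_dim), u = as.integer(u),
                 input_shape = input_shape, class_labels = class_labels,
                 blocks = list(), heads = list(), stages = list()),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat("cascade model:", length(x$blocks), "feature block(s),",
      length(x$heads), "output block(s); u =", x$u, "\n")
  for (h in x$heads)
    cat("  stage", h$stage, "-> head width", h$k, "on", h$depth, "block(s)\n")
  invisible(x)
}

#' Describe one cascade stage
#'
#' @param level hierarchy level this stage solves (1 = coarsest).
#' @param n_classes head width: the number of clusters at that level.
#' @param width width of the affine feature block added for this stage.
#' @param epochs training epochs for the stage.
#' @param scope `"new-only"` freezes previously trained blocks (cascade
#'   style); `"all"` fine-tunes everything (nested style).
#' @return a `stage_spec` list.
#' @export
stage_spec <- function(level, n_classes, width, epochs = 10L,
                       scope = c("new-only", "all")) {
  scope <- match.arg(scope)
  stopifnot(level >= 1L, n_classes >= 2L, width >= 1L, epochs >= 0L)
  structure(list(level = as.integer(level), n_classes = as.integer(n_classes),
                 width = as.integer(width), epochs = as.integer(epochs),
                 scope = scope),
            class = "stage_spec")
}

add_block <- function(model, width) {
  n_in <- if (length(model$blocks)) ncol(model$blocks[[length(model$blocks)]]$W)
          else model$input_dim
  model$blocks[[length(model$blocks) + 1L]] <- init_affine(n_in, width)
  model
}

add_head <- function(model, n_classes, stage, depth = length(model$blocks)) {
  if (depth < 1L) stop("cannot attach a head to a model with no feature block")
  top_width <- ncol(model$blocks[[depth]]$W)
  model$heads[[length(model$heads) + 1L]] <-
    list(P = init_affine(top_width, model$u),
         H = init_affine(model$u, n_classes),
         k = as.integer(n_classes), depth = as.integer(depth),
         stage = as.integer(stage))
  model
}

#' Grow a cascade model by one stage
#'
#' Appends a freshly initialised feature block and attaches a new output
#' block (projection to `u`, ReLU, affine head, softmax) for the stage's
#' class count. Existing blocks and heads are untouched; earlier heads are
#' retained so stage-wise predictions remain available after growth.
#'
#' @param model a `cascade_model`.
#' @param stage a [stage_spec()]; its `level` must equal the current depth
#'   plus one.
#' @param seed integer seed for the new parameters' initialisation.
#' @return the grown `cascade_model`.
#' @export
grow_model <- function(model, stage, seed) {
  stopifnot(inherits(model, "cascade_model"), inherits(stage, "stage_spec"))
  if (stage$level != length(model$blocks) + 1L)
    stop("stage level must be current depth + 1 (got level ", stage$level,
         " at depth ", length(model$blocks), ")")
  set.seed(as.integer(seed))
  model <- add_block(model, stage$width)
  model <- add_head(model, stage$n_classes, stage = length(model$heads) + 1L)
  model$stages[[length(model$stages) + 1L]] <- stage
  model
}

# forward pass through blocks 1..depth of the given head; keeps every
# intermediate needed by the backward pass
forward_cascade <- function(model, X, head_idx = length(model$heads)) {
  head <- model$heads[[head_idx]]
  Z <- X
  pre <- vector("list", head$depth)
  post <- vector("list", head$depth)
  for (j in seq_len(head$depth)) {
    A <- sweep(Z %*% model$blocks[[j]]$W, 2L, model$blocks[[j]]$b, "+")
    Z <- A * (A > 0)
    pre[[j]] <- A; post[[j]] <- Z
  }
  latent <- sweep(Z %*% head$P$W, 2L, head$P$b, "+")
  hidden <- latent * (latent > 0)
  logits <- sweep(hidden %*% head$H$W, 2L, head$H$b, "+")
  probs <- softmax_rows(logits)
  list(pre = pre, post = post, latent = latent, hidden = hidden,
       logits = logits, probs = probs, head = head)
}

# backward pass: dlogits (m x k) from the classification term and
# dlatent_extra (m x u, or NULL) from the regression term. Returns grads
# for blocks 1..depth and for the head, plus the input gradient.
backward_cascade <- function(model, X, fwd, dlogits, dlatent_extra = NULL,
                             want_input_grad = FALSE) {
  head <- fwd$head
  gH <- list(W = crossprod(fwd$hidden, dlogits), b = colSums(dlogits))
  dhidden <- dlogits %*% t(head$H$W)
  dlatent <- dhidden * (fwd$latent > 0)
  if (!is.null(dlatent_extra)) dlatent <- dlatent + dlatent_extra
  top <- if (head$depth >= 1L) fwd$post[[head$depth]] else X
  gP <- list(W = crossprod(top, dlatent), b = colSums(dlatent))
  dZ <- dlatent %*% t(head$P$W)
  gblocks <- vector("list", head$depth)
  for (j in rev(seq_len(head$depth))) {
    dA <- dZ * (fwd$pre[[j]] > 0)
    inp <- if (j == 1L) X else fwd$post[[j - 1L]]
    gblocks[[j]] <- list(W = crossprod(inp, dA), b = colSums(dA))
    dZ <- dA %*% t(model$blocks[[j]]$W)
  }
  list(blocks = gblocks, P = gP, H = gH,
       input = if (want_input_grad) dZ else NULL)
}

# Adam state handling: moments mirror the parameter structure
adam_new_state <- function() list(t = 0L, m = list(), v = list())

adam_update <- function(param, grad, state, key, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state$m[[key]])) {
    state$m[[key]] <- lapply(grad, function(g) g * 0)
    state$v[[key]] <- lapply(grad, function(g) g * 0)
  }
  t <- state$t
  for (nm in names(grad)) {
    state$m[[key]][[nm]] <- beta1 * state$m[[key]][[nm]] + (1 - beta1) * grad[[nm]]
    state$v[[key]][[nm]] <- beta2 * state$v[[key]][[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- state$m[[key]][[nm]] / (1 - beta1^t)
    vhat <- state$v[[key]][[nm]] / (1 - beta2^t)
    param[[nm]] <- param[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(param = param, state = state)
}

#' Checksums of the model's parameter blocks
#'
#' One hash per feature block and per output block, used to verify the
#' freeze contract: frozen blocks must be bit-identical across a stage.
#'
#' @param model a `cascade_model`.
#' @return named character vector of hashes (`block1..`, `head1..`).
#' @export
block_checksums <- function(model) {
  stopifnot(inherits(model, "cascade_model"))
  cs <- c(
    vapply(model$blocks, function(b) rlang::hash(b), character(1L)),
    vapply(model$heads, function(h) rlang::hash(list(h$P, h$H)), character(1L))
  )
  names(cs) <- c(paste0("block", seq_along(model$blocks)),
                 paste0("head", seq_along(model$heads)))
  cs
}
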