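#' Per-level targets from leaf targets
#'
#' Column `l` holds each sample's ancestor cluster id at hierarchy level
#' `l`; the last column equals the leaf problem's targets.
#'
#' @param hierarchy a `label_hierarchy`.
#' @param leaf_targets integer vector of leaf indices (1-based positions in
#'   `hierarchy$leaves`).
#' @return integer matrix (m x L).
#' @export
build_stage_targets <- function(hierarchy, leaf_targets) {
  validate_label_hierarchy(hierarchy)
  leaf_targets <- as.integer(leaf_targets)
  n <- length(hierarchy$leaves)
  if (any(leaf_targets < 1L | leaf_targets > n))
    stop("leaf target outside 1..", n)
  out <- vapply(seq_len(hierarchy$L),
                function(l) unname(hierarchy$levels[[l]][leaf_targets]),
                integer(length(leaf_targets)))
  matrix(out, ncol = hierarchy$L)
}

# per-cluster regression targets at one level: the centroid of member-leaf
# embeddings (a singleton cluster's centroid is the leaf's own vector)
cluster_embedding_targets <- function(hierarchy, level, embeddings) {
  emb <- validate_embedding_table(embeddings)
  miss <- setdiff(hierarchy$leaves, rownames(emb))
  if (length(miss))
    stop("no embedding for leaf label(s): ", paste(miss, collapse = ", "))
  members <- hierarchy_members(hierarchy, level)
  t(vapply(members, function(g) colMeans(emb[g, , drop = FALSE]),
           numeric(ncol(emb))))
}

#' Train one stage of a cascade model
#'
#' Runs seeded minibatch gradient descent (Adam) on the combined objective
#' `alpha * cosine_alignment + beta * weighted_cross_entropy` for the
#' stage's head. In `new-only` scope only the newest feature block and the
#' stage's output block receive updates (cascade style); in `all` scope
#' every feature block up to the head's depth is fine-tuned (nested style).
#' Earlier stages' output blocks are never touched.
#'
#' @param model a `cascade_model` whose last head is the stage to train.
#' @param X numeric matrix (m x input_dim) of training inputs.
#' @param y integer targets in `1..k` for the stage's class count `k`.
#' @param epochs number of passes over the data (0 returns the model
#'   unchanged).
#' @param scope `"new-only"` or `"all"`.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param alpha,beta loss weights (see [resolve_weight_schedule()]).
#' @param emb_targets optional k x u matrix of per-class regression target
#'   embeddings; required when `alpha > 0`.
#' @param class_weights optional positive per-class weights for the
#'   cross-entropy term.
#' @param seed integer seed controlling shuffling (and nothing else).
#' @param head_idx which head to train (default: the newest).
#' @return list with the updated `model` and `history`, the per-epoch mean
#'   combined loss (length `epochs`).
#' @export
train_stage <- function(model, X, y, epochs, scope = c("new-only", "all"),
                        lr = 1e-3, batch_size = 64L, alpha = 0, beta = 1,
                        emb_targets = NULL, class_weights = NULL, seed = 1L,
                        head_idx = length(model$heads)) {
  stopifnot(inherits(model, "cascade_model"))
  scope <- match.arg(scope)
  X <- as.matrix(X)
  y <- as.integer(y)
  head <- model$heads[[head_idx]]
  k <- head$k
  if (any(y < 1L | y > k)) stop("stage target outside 1..", k)
  if (alpha > 0 && is.null(emb_targets))
    stop("alpha > 0 requires per-class embedding targets")
  if (!is.null(emb_targets)) {
    emb_targets <- as.matrix(emb_targets)
    if (nrow(emb_targets) != k || ncol(emb_targets) != model$u)
      stop("emb_targets must be ", k, " x ", model$u)
  }
  if (is.null(class_weights)) class_weights <- rep(1, k)
  if (length(class_weights) != k || any(class_weights <= 0))
    stop("class_weights must be positive, one per stage class")
  epochs <- as.integer(epochs)
  if (epochs == 0L) return(list(model = model, history = numeric(0)))

  trainable <- if (scope == "new-only") head$depth else seq_len(head$depth)
  m <- nrow(X)
  state <- adam_new_state()
  history <- numeric(epochs)
  set.seed(as.integer(seed))
  for (ep in seq_len(epochs)) {
    idx <- sample.int(m)
    splits <- split(idx, ceiling(seq_along(idx) / batch_size))
    ep_loss <- 0; ep_n <- 0L
    for (batch in splits) {
      Xb <- X[batch, , drop = FALSE]
      yb <- y[batch]
      mb <- length(batch)
      fwd <- forward_cascade(model, Xb, head_idx)
      # classification term and its gradient on the logits
      w <- class_weights[yb]
      p_true <- pmax(fwd$probs[cbind(seq_len(mb), yb)], 1e-12)
      cce <- sum(w * -log(p_true)) / sum(w)
      onehot <- matrix(0, mb, k); onehot[cbind(seq_len(mb), yb)] <- 1
      dlogits <- beta * (w / sum(w)) * (fwd$probs - onehot)
      # regression term on the pre-ReLU projection (the latent space)
      reg <- 0; dlatent_extra <- NULL
      if (alpha > 0) {
        tgt <- emb_targets[yb, , drop = FALSE]
        nl <- pmax(row_norms(fwd$latent), 1e-12)
        nt <- row_norms(tgt)
        cosine <- rowSums(fwd$latent * tgt) / (nl * nt)
        reg <- mean(1 - cosine)
        dlatent_extra <- -(alpha / mb) *
          (tgt / (nl * nt) - (cosine / nl^2) * fwd$latent)
      }
      loss <- alpha * reg + beta * cce
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", ep,
             "; lower the learning rate")
      grads <- backward_cascade(model, Xb, fwd, dlogits, dlatent_extra)
      state$t <- state$t + 1L
      for (j in trainable) {
        upd <- adam_update(model$blocks[[j]], grads$blocks[[j]], state,
                           paste0("block", j), lr)
        model$blocks[[j]] <- upd$param; state <- upd$state
      }
      upd <- adam_update(model$heads[[head_idx]]$P, grads$P, state, "P", lr)
      model$heads[[head_idx]]$P <- upd$param; state <- upd$state
      upd <- adam_update(model$heads[[head_idx]]$H, grads$H, state, "H", lr)
      model$heads[[head_idx]]$H <- upd$param; state <- upd$state
      ep_loss <- ep_loss + loss * mb; ep_n <- ep_n + mb
    }
    history[ep] <- ep_loss / ep_n
  }
  list(model = model, history = history)
}

mechanism_names <- c("E2E", "HE2E", "CL", "SCL", "NCL", "NSCL", "RHCL")

# named architecture presets; widths/epochs recycle across stages
model_presets <- list(
  # stage-1 width below the leaf-class count: the coarse representation is
  # a real bottleneck, so the grouping that shapes it matters
  fixture_tiny = list(widths = c(6L, 32L), u = 16L, epochs = c(20L, 15L),
                      lr = 5e-3, batch_size = 128L, alpha = 2),
  cifar_small = list(widths = 256L, u = 300L, epochs = 50L, lr = 1e-3,
                     batch_size = 128L, alpha = 1),
  chexpert_small = list(widths = c(512L, 256L, 256L, 128L), u = 200L,
                        epochs = c(35L, 40L, 45L, 50L), lr = 1e-4,
                        batch_size = 64L, alpha = 1),
  tabular_1d = list(widths = c(16L, 32L, 64L, 32L), u = 16L, epochs = 20L,
                    lr = 1e-4, batch_size = 128L, alpha = 1)
)

#' Named architecture presets
#'
#' Returns the width/epoch/learning-rate bundle of a preset, suitable for
#' splicing into [cascade_config()]. `fixture_tiny` is sized for the
#' planted synthetic fixtures; `cifar_small`, `chexpert_small` and
#' `tabular_1d` mirror the block-width schedules used for the benchmark
#' problems and are provided as starting points, not tuned references.
#'
#' @param name one of `"fixture_tiny"`, `"cifar_small"`,
#'   `"chexpert_small"`, `"tabular_1d"`.
#' @return named list of [cascade_config()] arguments.
#' @export
model_preset <- function(name) {
  if (!name %in% names(model_presets))
    stop("unknown model preset '", name, "'; available: ",
         paste(names(model_presets), collapse = ", "))
  model_presets[[name]]
}

#' Configuration for cascade training
#'
#' @param mechanism one of `"E2E"`, `"HE2E"`, `"CL"`, `"SCL"`, `"NCL"`,
#'   `"NSCL"`, `"RHCL"`.
#' @param widths feature-block widths, recycled across stages.
#' @param u embedding / projection dimension.
#' @param epochs per-stage epochs (scalar or vector, recycled).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param alpha regression weight; `beta` follows the schedule of
#'   [resolve_weight_schedule()]. Forced to 0 for E2E/CL/NCL (no semantic
#'   loss in those mechanisms).
#' @param class_weighting `"proportional"` (weights from training counts)
#'   or `"none"`.
#' @param depth number of feature blocks for the non-hierarchical
#'   mechanisms (E2E/HE2E/CL/NCL); hierarchical mechanisms take their stage
#'   count from the hierarchy.
#' @param rhcl_scope `"new-only"` (frozen cascade, the default: RHCL is
#'   the randomised counterpart of SCL) or `"all"` (nested).
#' @param seed global seed; per-stage seeds are derived from it.
#' @return a `cascade_config` list.
#' @export
cascade_config <- function(mechanism, widths = 32L, u = 16L, epochs = 10L,
                           lr = 1e-3, batch_size = 64L, alpha = 0,
                           class_weighting = c("proportional", "none"),
                           depth = length(widths), rhcl_scope = "new-only",
                           seed = 1L) {
  mechanism <- match.arg(toupper(mechanism), mechanism_names)
  class_weighting <- match.arg(class_weighting)
  if (alpha < 0 || alpha > 7) stop("alpha must lie in [0, 7]")
  structure(list(mechanism = mechanism, widths = as.integer(widths),
                 u = as.integer(u), epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), alpha = alpha,
                 class_weighting = class_weighting, depth = as.integer(depth),
                 rhcl_scope = rhcl_scope, seed = as.integer(seed)),
            class = "cascade_config")
}

#' Train a classifier under one of the seven mechanisms
#'
#' Coarse-to-fine mechanisms (SCL, NSCL, RHCL) run one stage per hierarchy
#' level with head widths equal to the level's cluster counts; CL and NCL
#' run the same staged growth but every stage solves the full leaf problem;
#' E2E and HE2E build the full depth at once and train a single stage with
#' everything trainable, HE2E adding the combined embedding-regression
#' loss. RHCL first randomises the hierarchy (seeded), keeping the cluster
#' size multisets.
#'
#' @param X numeric matrix (m x features).
#' @param y integer leaf targets (1-based positions in `hierarchy$leaves`
#'   or `1..n_classes` for the non-hierarchical mechanisms).
#' @param config a [cascade_config()].
#' @param hierarchy a `label_hierarchy`; required for SCL/NSCL/RHCL and
#'   for severity evaluation.
#' @param embeddings label embedding table; required whenever `alpha > 0`
#'   (per-cluster regression targets are centroids of member-leaf vectors).
#' @param n_classes leaf class count for mechanisms run without a
#'   hierarchy (defaults to `max(y)`).
#' @param input_shape optional raster shape passed to [new_cascade_model()].
#' @return list with `model` (a `cascade_model`) and `report` (mechanism,
#'   head widths, per-stage loss histories, seeds, the hierarchy actually
#'   trained on — for RHCL the randomised one).
#' @export
train_cascade <- function(X, y, config, hierarchy = NULL, embeddings = NULL,
                          n_classes = NULL, input_shape = NULL) {
  stopifnot(inherits(config, "cascade_config"))
  X <- as.matrix(X)
  y <- as.integer(y)
  mech <- config$mechanism
  semantic <- mech %in% c("SCL", "NSCL", "RHCL")
  if (semantic && is.null(hierarchy))
    stop(mech, " requires a label hierarchy")
  alpha <- if (mech %in% c("E2E", "CL", "NCL")) 0 else config$alpha
  lw <- resolve_weight_schedule(alpha)
  if (lw$alpha > 0 && is.null(embeddings))
    stop("alpha > 0 requires a label embedding table")

  train_h <- hierarchy
  if (mech == "RHCL")
    train_h <- random_hierarchy(hierarchy, derive_seed(config$seed, 97L))

  if (!is.null(train_h)) {
    n_classes <- length(train_h$leaves)
  } else if (is.null(n_classes)) n_classes <- max(y)

  # stage plan: head widths, per-stage targets, scopes
  if (semantic) {
    n_stage <- train_h$L
    stage_targets <- build_stage_targets(train_h, y)
    head_widths <- vapply(seq_len(n_stage), function(l) n_clusters(train_h, l),
                          integer(1L))
    scope <- if (mech == "SCL" ||
                 (mech == "RHCL" && identical(config$rhcl_scope, "new-only")))
      "new-only" else "all"
    scopes <- rep(scope, n_stage)
  } else if (mech %in% c("CL", "NCL")) {
    n_stage <- config$depth
    stage_targets <- matrix(y, nrow = length(y), ncol = n_stage)
    head_widths <- rep(n_classes, n_stage)
    scopes <- rep(if (mech == "CL") "new-only" else "all", n_stage)
  } else {                                  # E2E / HE2E: one stage, full depth
    n_stage <- 1L
    stage_targets <- matrix(y, ncol = 1L)
    head_widths <- n_classes
    scopes <- "all"
  }
  widths <- rep_len(config$widths, if (mech %in% c("E2E", "HE2E"))
    config$depth else n_stage)
  epochs <- rep_len(config$epochs, n_stage)

  model <- new_cascade_model(ncol(X), config$u, input_shape = input_shape,
                             class_labels = train_h$leaves %||% NULL)
  if (mech %in% c("E2E", "HE2E")) {
    set.seed(derive_seed(config$seed, 1L))
    for (w in widths) model <- add_block(model, w)
    model <- add_head(model, n_classes, stage = 1L)
    model$stages[[1L]] <- stage_spec(1L, n_classes, widths[length(widths)],
                                     epochs[1L], "all")
  }

  histories <- vector("list", n_stage)
  for (s in seq_len(n_stage)) {
    if (!mech %in% c("E2E", "HE2E")) {
      model <- grow_model(model,
                          stage_spec(s, head_widths[s], widths[s], epochs[s],
                                     scopes[s]),
                          seed = derive_seed(config$seed, s))
    }
    ys <- stage_targets[, s]
    cw <- if (config$class_weighting == "proportional")
      class_weights_from_counts(tabulate(ys, nbins = head_widths[s]))
    else NULL
    emb <- NULL
    if (lw$alpha > 0) {
      emb <- if (semantic)
        cluster_embedding_targets(train_h, s, embeddings)
      else {
        lvl <- if (!is.null(train_h)) train_h$L else NULL
        if (!is.null(train_h))
          cluster_embedding_targets(train_h, lvl, embeddings)
        else validate_embedding_table(embeddings)
      }
    }
    fit <- train_stage(model, X, ys, epochs = epochs[s], scope = scopes[s],
                       lr = config$lr, batch_size = config$batch_size,
                       alpha = lw$alpha, beta = lw$beta, emb_targets = emb,
                       class_weights = cw,
                       seed = derive_seed(config$seed, 100L + s))
    model <- fit$model
    histories[[s]] <- fit$history
  }
  report <- list(mechanism = mech, head_widths = head_widths,
                 scopes = scopes, histories = histories,
                 seed = config$seed, alpha = lw$alpha, beta = lw$beta,
                 config = unclass(config), trained_hierarchy = train_h)
  list(model = model, report = report)
}

#' Leaf predictions of the final stage
#'
#' Argmax of the final head's softmax scores; ties break toward the lowest
#' class index.
#'
#' @param model a trained `cascade_model`.
#' @param X input matrix.
#' @return list with `leaf` (integer vector) and `scores` (m x K matrix,
#'   rows on the simplex).
#' @export
predict_leaf <- function(model, X) {
  stopifnot(inherits(model, "cascade_model"))
  if (!length(model$heads)) stop("model has no trained head")
  fwd <- forward_cascade(model, as.matrix(X))
  list(leaf = max.col(fwd$probs, ties.method = "first"), scores = fwd$probs)
}

#' Per-level predictions
#'
#' `project-leaf` mode maps the final leaf prediction to its ancestor at
#' every hierarchy level, giving hierarchy-consistent rows for any model;
#' `stage-heads` mode reads each stage's own head (only for cascade-style
#' models whose stage count matches the hierarchy depth).
#'
#' @param model a trained `cascade_model`.
#' @param hierarchy a `label_hierarchy` of depth L.
#' @param X input matrix.
#' @param mode `"project-leaf"` (default) or `"stage-heads"`.
#' @return integer matrix (m x L) of cluster ids.
#' @export
predict_levels <- function(model, hierarchy, X,
                           mode = c("project-leaf", "stage-heads")) {
  mode <- match.arg(mode)
  validate_label_hierarchy(hierarchy)
  X <- as.matrix(X)
  if (mode == "project-leaf") {
    leaf <- predict_leaf(model, X)$leaf
    return(build_stage_targets(hierarchy, leaf))
  }
  if (length(model$heads) != hierarchy$L)
    stop("stage-heads mode needs one head per hierarchy level ",
         "(model has ", length(model$heads), ", hierarchy depth ",
         hierarchy$L, "); single-stage models support project-leaf only")
  out <- vapply(seq_len(hierarchy$L), function(l) {
    fwd <- forward_cascade(model, X, head_idx = l)
    max.col(fwd$probs, ties.method = "first")
  }, integer(nrow(X)))
  matrix(out, ncol = hierarchy$L)
}
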