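#' Configuration of the planted-hierarchy generator
#'
#' The generator emulates the two ingredients the cascade needs: label
#' embeddings whose geometry carries a two-level group structure, and a
#' classification dataset whose class-conditional feature distributions
#' carry the same structure. Supergroup centres sit at exact pairwise
#' distance `delta_between` (mutually orthogonal directions, so the
#' separation is guaranteed, not merely expected); leaves scatter around
#' their centre at scale `delta_within`; samples add isotropic Gaussian
#' noise of scale `noise_sigma`. `delta_between >> delta_within` is the
#' recovery regime in which clustering provably finds the supergroups.
#'
#' @param n_super number of supergroups (>= 2).
#' @param leaves_per_super leaves per supergroup (>= 2).
#' @param u embedding dimension (must be >= n_super).
#' @param delta_between supergroup-centre separation (> 0).
#' @param delta_within leaf spread around its centre (> 0).
#' @param feature_dim dataset feature dimension (must be >= n_super).
#' @param noise_sigma sample noise scale (> 0).
#' @param n_per_class samples per leaf class.
#' @param imbalanced draw per-class counts from a seeded multinomial
#'   instead of exactly `n_per_class` each.
#' @param seed integer seed; all outputs are deterministic given it.
#' @return a `planted_config` list.
#' @export
planted_config <- function(n_super = 2L, leaves_per_super = 2L, u = 16L,
                           delta_between = 10, delta_within = 0.1,
                           feature_dim = 16L, noise_sigma = 1,
                           n_per_class = 50L, imbalanced = FALSE, seed = 1L) {
  stopifnot(n_super >= 2L, leaves_per_super >= 2L,
            delta_between > 0, delta_within > 0, noise_sigma > 0,
            n_per_class >= 1L, u >= n_super, feature_dim >= n_super)
  structure(list(n_super = as.integer(n_super),
                 leaves_per_super = as.integer(leaves_per_super),
                 u = as.integer(u), delta_between = delta_between,
                 delta_within = delta_within,
                 feature_dim = as.integer(feature_dim),
                 noise_sigma = noise_sigma,
                 n_per_class = as.integer(n_per_class),
                 imbalanced = isTRUE(imbalanced), seed = as.integer(seed)),
            class = "planted_config")
}

planted_labels <- function(config) {
  as.vector(t(outer(seq_len(config$n_super), seq_len(config$leaves_per_super),
                    function(i, j) sprintf("s%d_l%d", i, j))))
}

# centres on mutually orthogonal directions scaled so every pairwise
# distance equals delta exactly
orthogonal_centres <- function(k, dim, delta) {
  Q <- qr.Q(qr(matrix(stats::rnorm(dim * k), dim, k)))
  t(Q) * (delta / sqrt(2))
}

planted_partition_hierarchy <- function(config) {
  labels <- planted_labels(config)
  super <- rep(seq_len(config$n_super), each = config$leaves_per_super)
  new_label_hierarchy(labels, list(super, seq_along(labels)))
}

#' Simulate label embeddings with planted supergroups
#'
#' @param config a [planted_config()].
#' @return list with `table` (label embedding table, labels `s{i}_l{j}`)
#'   and `partition` (integer vector: true supergroup of each label).
#' @export
simulate_label_embeddings <- function(config) {
  stopifnot(inherits(config, "planted_config"))
  set.seed(derive_seed(config$seed, 11L))
  centres <- orthogonal_centres(config$n_super, config$u, config$delta_between)
  labels <- planted_labels(config)
  vecs <- matrix(NA_real_, length(labels), config$u,
                 dimnames = list(labels, NULL))
  row <- 0L
  for (i in seq_len(config$n_super)) {
    for (j in seq_len(config$leaves_per_super)) {
      row <- row + 1L
      vecs[row, ] <- centres[i, ] +
        stats::rnorm(config$u) * config$delta_within
    }
  }
  list(table = validate_embedding_table(vecs),
       partition = rep(seq_len(config$n_super),
                       each = config$leaves_per_super))
}

#' Simulate a hierarchically structured classification dataset
#'
#' Class means are placed hierarchically in feature space (supergroup
#' centres `delta_between` apart, leaf means scattered at `delta_within`);
#' samples add Gaussian noise of scale `noise_sigma`. With
#' `delta_within << noise_sigma << delta_between` a classifier's
#' confusions fall almost entirely within supergroups — the error
#' structure the severity metric is designed to detect.
#'
#' @param config a [planted_config()].
#' @param n_per_class optional override of the per-class sample count.
#' @param sample_seed optional separate seed for the noise draws (the
#'   class means depend only on `config$seed`), so train and test sets
#'   share means but not samples.
#' @return list with `X` (numeric matrix), `y` (integer leaf targets,
#'   positions in the hierarchy's leaf order), `hierarchy` (the planted
#'   2-level `label_hierarchy`), `labels`, and `means` (leaf mean matrix).
#' @export
simulate_classification_dataset <- function(config, n_per_class = NULL,
                                            sample_seed = NULL) {
  stopifnot(inherits(config, "planted_config"))
  n_per_class <- as.integer(n_per_class %||% config$n_per_class)
  n_leaves <- config$n_super * config$leaves_per_super
  set.seed(derive_seed(config$seed, 23L))
  centres <- orthogonal_centres(config$n_super, config$feature_dim,
                                config$delta_between)
  means <- matrix(NA_real_, n_leaves, config$feature_dim)
  row <- 0L
  for (i in seq_len(config$n_super)) {
    for (j in seq_len(config$leaves_per_super)) {
      row <- row + 1L
      means[row, ] <- centres[i, ] +
        stats::rnorm(config$feature_dim) * config$delta_within
    }
  }
  set.seed(derive_seed(sample_seed %||% config$seed, 29L))
  counts <- if (config$imbalanced) {
    total <- n_leaves * n_per_class
    prob <- as.vector(stats::rmultinom(1L, 60L, rep(1 / n_leaves, n_leaves)))
    pmax(1L, as.vector(stats::rmultinom(1L, total, (prob + 1) / sum(prob + 1))))
  } else rep(n_per_class, n_leaves)
  y <- rep(seq_len(n_leaves), times = counts)
  X <- means[y, , drop = FALSE] +
    matrix(stats::rnorm(length(y) * config$feature_dim), length(y)) *
    config$noise_sigma
  hierarchy <- planted_partition_hierarchy(config)
  rownames(means) <- hierarchy$leaves
  list(X = X, y = y, hierarchy = hierarchy, labels = hierarchy$leaves,
       means = means)
}

#' Construct a rectangle mask pair with known overlap
#'
#' Two equal-area rectangles on a common grid, horizontally offset so the
#' intersection is an exact pixel count; the implied IOU is returned in
#' closed form alongside the masks.
#'
#' @param shape `c(height, width)` of the grid.
#' @param overlap_fraction fraction of each rectangle's width shared, in
#'   `[0, 1]` (1 = identical masks, 0 = disjoint).
#' @param seed integer seed (places the rectangles vertically).
#' @param rect_width rectangle width in pixels (default: a third of the
#'   grid width); both rectangles must fit side by side at the requested
#'   overlap or the geometry is rejected.
#' @return list with logical matrices `a`, `b` and the exact `iou`.
#' @export
simulate_mask_pair <- function(shape, overlap_fraction, seed = 1L,
                               rect_width = NULL) {
  stopifnot(length(shape) == 2L, all(shape >= 2L))
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must lie in [0, 1]")
  h <- as.integer(shape[[1L]]); w <- as.integer(shape[[2L]])
  wa <- as.integer(rect_width %||% max(1L, w %/% 3L))
  if (wa < 1L || wa > w) stop("infeasible geometry: rect_width outside 1..", w)
  ov <- as.integer(round(overlap_fraction * wa))
  if (2L * wa - ov > w)
    stop("infeasible geometry: rectangles of width ", wa,
         " with overlap ", ov, " do not fit in width ", w)
  hh <- max(1L, h %/% 2L)
  set.seed(as.integer(seed))
  top <- sample.int(h - hh + 1L, 1L)
  rows <- top:(top + hh - 1L)
  a <- matrix(FALSE, h, w); b <- matrix(FALSE, h, w)
  a[rows, 1:wa] <- TRUE
  b[rows, (wa - ov + 1L):(2L * wa - ov)] <- TRUE
  list(a = a, b = b, iou = ov / (2 * wa - ov))
}

fixture_presets <- list(
  tiny = list(n_super = 3L, leaves_per_super = 2L, u = 8L,
              delta_between = 10, delta_within = 0.5, feature_dim = 8L,
              noise_sigma = 1, n_per_class = 40L, imbalanced = FALSE),
  recovery = list(n_super = 4L, leaves_per_super = 3L, u = 16L,
                  delta_between = 20, delta_within = 1, feature_dim = 16L,
                  noise_sigma = 2, n_per_class = 200L, imbalanced = FALSE),
  imbalanced = list(n_super = 3L, leaves_per_super = 2L, u = 8L,
                    delta_between = 10, delta_within = 0.5, feature_dim = 8L,
                    noise_sigma = 1, n_per_class = 40L, imbalanced = TRUE)
)

#' Write a self-contained fixture bundle to disk
#'
#' Generates embeddings (word2vec text), the planted hierarchy (JSON),
#' train/test CSVs, a mask pair (PNG) and a manifest with content hashes,
#' so every CLI subcommand can run offline from one directory.
#'
#' @param preset `"tiny"`, `"recovery"` or `"imbalanced"`.
#' @param seed integer seed; identical seeds give identical manifests.
#' @param out_dir output directory (created if missing).
#' @return the manifest list, invisibly; files are written under
#'   `out_dir`.
#' @export
make_fixture_bundle <- function(preset, seed, out_dir) {
  if (!preset %in% names(fixture_presets))
    stop("unknown preset '", preset, "'; available: ",
         paste(names(fixture_presets), collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- fixture_presets[[preset]]
  config <- do.call(planted_config, c(p, list(seed = as.integer(seed))))

  emb <- simulate_label_embeddings(config)
  train <- simulate_classification_dataset(config,
                                           sample_seed = derive_seed(seed, 1L))
  test <- simulate_classification_dataset(
    config, n_per_class = max(10L, config$n_per_class %/% 4L),
    sample_seed = derive_seed(seed, 2L))
  masks <- simulate_mask_pair(c(32L, 32L), overlap_fraction = 0.5,
                              seed = derive_seed(seed, 3L))

  paths <- list(
    embeddings = file.path(out_dir, "embeddings.txt"),
    hierarchy = file.path(out_dir, "hierarchy.json"),
    labels = file.path(out_dir, "labels.txt"),
    train = file.path(out_dir, "train.csv"),
    test = file.path(out_dir, "test.csv"),
    mask_a = file.path(out_dir, "mask_a.png"),
    mask_b = file.path(out_dir, "mask_b.png"),
    config = file.path(out_dir, "config.json")
  )
  write_word2vec(emb$table, paths$embeddings)
  write_hierarchy_json(train$hierarchy, paths$hierarchy)
  writeLines(train$hierarchy$leaves, paths$labels)
  write_dataset_csv(train, paths$train)
  write_dataset_csv(test, paths$test)
  write_mask_png(masks$a, paths$mask_a)
  write_mask_png(masks$b, paths$mask_b)
  jsonlite::write_json(c(unclass(config), list(preset = preset)),
                       paths$config, auto_unbox = TRUE, pretty = TRUE)

  manifest <- list(
    preset = preset, seed = as.integer(seed),
    mask_iou = masks$iou,
    files = lapply(paths, function(f)
      list(name = basename(f),
           hash = rlang::hash(readBin(f, "raw", file.size(f)))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

write_dataset_csv <- function(data, path) {
  df <- as.data.frame(data$X)
  names(df) <- sprintf("f%02d", seq_len(ncol(data$X)))
  df$label <- data$labels[data$y]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a tabular classification dataset written by the fixture generator
#'
#' Expects a header row and a `label` column holding class names.
#'
#' @param path CSV path.
#' @param leaves optional leaf-label order fixing the integer coding of
#'   `y` (defaults to order of first appearance).
#' @return list with `X`, `y` and `labels`.
#' @export
read_dataset_csv <- function(path, leaves = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("dataset CSV needs a 'label' column")
  labels <- as.character(df$label)
  leaves <- leaves %||% unique(labels)
  y <- match(labels, leaves)
  if (anyNA(y)) stop("dataset contains labels outside the leaf set")
  X <- as.matrix(df[setdiff(names(df), "label")])
  storage.mode(X) <- "double"
  list(X = X, y = y, labels = leaves)
}
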