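#' Construct a label hierarchy from per-level partitions
#'
#' A label hierarchy is an ordered list of nested partitions of the leaf
#' label set, coarse to fine; level `L` (the deepest) is the leaf problem.
#' Cluster ids are dense integers assigned by order of first leaf
#' appearance, so identical structures print identically.
#'
#' @param leaves character vector of leaf labels (unique).
#' @param levels list of integer vectors, one per level, each of length
#'   `length(leaves)` giving the cluster id of every leaf at that level.
#' @return an object of class `label_hierarchy` with fields `leaves`,
#'   `levels` (named integer vectors) and `L`.
#' @export
new_label_hierarchy <- function(leaves, levels) {
  stopifnot(is.character(leaves), length(leaves) >= 1L, is.list(levels))
  if (anyDuplicated(leaves)) stop("leaf labels must be unique")
  levels <- lapply(levels, function(a) {
    a <- as.integer(densify_ids(a))
    names(a) <- leaves
    a
  })
  h <- structure(list(leaves = leaves, levels = levels, L = length(levels)),
                 class = "label_hierarchy")
  validate_label_hierarchy(h)
  h
}

#' Validate label-hierarchy invariants
#'
#' Checks full coverage of the leaf set at every level, non-decreasing
#' cluster counts, that the deepest level attains the maximum count, and
#' nesting: every level-(l+1) cluster lies inside exactly one level-l
#' cluster.
#'
#' @param h a `label_hierarchy`.
#' @return `h` invisibly, or an error describing the violated invariant.
#' @export
validate_label_hierarchy <- function(h) {
  if (!inherits(h, "label_hierarchy")) stop("not a label_hierarchy")
  n <- length(h$leaves)
  counts <- integer(h$L)
  for (l in seq_len(h$L)) {
    a <- h$levels[[l]]
    if (length(a) != n || !identical(names(a), h$leaves))
      stop("level ", l, " does not cover the leaf set exactly once")
    if (!identical(as.integer(a), as.integer(densify_ids(a))))
      stop("level ", l, " cluster ids are not dense first-appearance ids")
    counts[l] <- max(a)
  }
  if (h$L > 1L && any(diff(counts) < 0L))
    stop("cluster counts must be non-decreasing across levels")
  if (counts[h$L] != max(counts))
    stop("deepest level must have the maximum cluster count")
  if (h$L > 1L) {
    for (l in seq_len(h$L - 1L)) {
      parents <- tapply(h$levels[[l]], h$levels[[l + 1L]],
                        function(p) length(unique(p)))
      if (any(parents != 1L))
        stop("nesting violated between levels ", l, " and ", l + 1L)
    }
  }
  invisible(h)
}

#' @export
print.label_hierarchy <- function(x, ...) {
  cat("label hierarchy:", length(x$leaves), "leaves,", x$L, "levels",
      "(cluster counts:", paste(vapply(x$levels, max, integer(1L)),
                                collapse = ", "), ")\n")
  invisible(x)
}

#' Number of clusters at one level
#' @param h a `label_hierarchy`.
#' @param level level index in `1..L`.
#' @return integer cluster count.
#' @export
n_clusters <- function(h, level) {
  stopifnot(inherits(h, "label_hierarchy"), level >= 1L, level <= h$L)
  max(h$levels[[level]])
}

#' Leaves of each cluster at one level
#' @inheritParams n_clusters
#' @return list indexed by cluster id, each element a character vector of
#'   member leaves.
#' @export
hierarchy_members <- function(h, level) {
  stopifnot(inherits(h, "label_hierarchy"), level >= 1L, level <= h$L)
  unname(split(h$leaves, h$levels[[level]]))
}

#' Cluster containing a leaf at a given level
#'
#' @param h a `label_hierarchy`.
#' @param leaf a leaf label present in `h`.
#' @param level level index in `1..L`.
#' @return the cluster id (integer) of the unique level-`level` cluster
#'   containing `leaf`.
#' @export
ancestor_at_level <- function(h, leaf, level) {
  stopifnot(inherits(h, "label_hierarchy"))
  if (!(leaf %in% h$leaves)) stop("unknown leaf: ", leaf)
  if (level < 1L || level > h$L) stop("level out of range 1..", h$L)
  unname(h$levels[[level]][[leaf]])
}

#' Cluster label embeddings into a dendrogram
#'
#' Agglomerative clustering of the label vectors. By default vectors are
#' L2-normalised and clustered with average linkage on cosine distance
#' (`1 - cosine similarity`), the natural geometry for word embeddings.
#'
#' @param table label embedding table (rownamed numeric matrix).
#' @param linkage one of `"average"`, `"complete"`, `"ward"` (Ward on
#'   squared distances, `stats::hclust` method `ward.D2`).
#' @param metric `"cosine"` or `"euclidean"`.
#' @param normalize L2-normalise rows before clustering (default TRUE).
#' @return an `hclust` object with `labels` set; deterministic for a given
#'   table and settings.
#' @export
build_dendrogram <- function(table,
                             linkage = c("average", "complete", "ward"),
                             metric = c("cosine", "euclidean"),
                             normalize = TRUE) {
  table <- validate_embedding_table(table)
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  if (nrow(table) < 2L) stop("need at least 2 labels to build a dendrogram")
  v <- if (normalize) l2_normalize_rows(table) else table
  d <- switch(metric,
    cosine = {
      vn <- l2_normalize_rows(v)
      dd <- 1 - tcrossprod(vn)
      dd[dd < 0] <- 0          # numerical guard near identical vectors
      stats::as.dist(dd)
    },
    euclidean = stats::dist(v)
  )
  method <- switch(linkage, average = "average", complete = "complete",
                   ward = "ward.D2")
  stats::hclust(d, method = method)
}

check_cut_counts <- function(counts, n) {
  counts <- as.integer(counts)
  if (length(counts) < 1L || any(is.na(counts)))
    stop("cluster counts must be a non-empty integer vector")
  if (any(counts < 2L)) stop("cluster counts must be at least 2")
  if (any(counts > n)) stop("cluster count exceeds the number of labels (", n, ")")
  d <- diff(counts)
  if (any(d < 0L)) stop("cluster counts must be non-decreasing")
  # repeats are only allowed as a trailing run of the final count
  rep_at <- which(d == 0L)
  if (length(rep_at) && any(counts[rep_at] != counts[length(counts)]))
    stop("repeated cluster counts are only allowed at the end")
  counts
}

#' Cut a dendrogram into a nested label hierarchy
#'
#' Each requested cluster count produces one level; cutting one tree at
#' several depths guarantees nesting by construction. A trailing repeated
#' count is allowed (some problem presets re-train the leaf stage) and
#' duplicates the finest partition.
#'
#' @param dendrogram an `hclust` from [build_dendrogram()].
#' @param cluster_counts increasing integer vector of per-level class
#'   counts, e.g. `c(2, 3, 10)`; a final repeated count is permitted.
#' @return a `label_hierarchy` with one level per count.
#' @export
cut_dendrogram <- function(dendrogram, cluster_counts) {
  if (!inherits(dendrogram, "hclust")) stop("expected an hclust dendrogram")
  n <- length(dendrogram$labels)
  counts <- check_cut_counts(cluster_counts, n)
  levels <- lapply(counts, function(k) {
    unname(stats::cutree(dendrogram, k = k))
  })
  new_label_hierarchy(dendrogram$labels, levels)
}

#' Build a label hierarchy from prior-knowledge (child, parent) edges
#'
#' Ingests a tree, typically flattened from a disease DAG, and stratifies
#' it by depth: level l groups every leaf under its depth-l ancestor (or
#' the leaf itself when the leaf sits shallower). A node listed with
#' several parents is resolved to its first-listed parent with a warning.
#'
#' @param edges two-column matrix/data.frame of character (child, parent)
#'   pairs, or a list of length-2 vectors.
#' @param leaf_labels character vector of the leaf labels.
#' @return a `label_hierarchy` whose levels are the depth strata.
#' @export
hierarchy_from_edges <- function(edges, leaf_labels) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.list(edges) && !is.matrix(edges))
    edges <- do.call(rbind, lapply(edges, function(e) matrix(e, 1L)))
  storage.mode(edges) <- "character"
  if (ncol(edges) != 2L) stop("edges must be (child, parent) pairs")
  children <- edges[, 1L]; parents <- edges[, 2L]
  if (anyDuplicated(children)) {
    dups <- unique(children[duplicated(children)])
    warning("node(s) with multiple listed parents resolved to the ",
            "first-listed parent: ", paste(dups, collapse = ", "))
    keep <- !duplicated(children)
    children <- children[keep]; parents <- parents[keep]
  }
  parent_of <- stats::setNames(parents, children)
  nodes <- union(children, parents)
  roots <- setdiff(parents, children)
  if (length(roots) != 1L)
    stop("edges must have exactly one root; found: ",
         paste(roots, collapse = ", "))
  missing_leaves <- setdiff(leaf_labels, children)
  if (length(missing_leaves))
    stop("orphan leaf (no path to the root): ",
         paste(missing_leaves, collapse = ", "))
  n_nodes <- length(nodes)
  # path from each leaf up to the root; a chain longer than the node count
  # means the parent map loops
  paths <- lapply(leaf_labels, function(leaf) {
    path <- leaf
    node <- leaf
    while (node %in% names(parent_of)) {
      node <- parent_of[[node]]
      path <- c(node, path)                 # root first
      if (length(path) > n_nodes) stop("cycle detected in edges near '", leaf, "'")
    }
    if (path[[1L]] != roots) stop("leaf '", leaf, "' does not reach the root")
    path
  })
  depths <- vapply(paths, length, integer(1L)) - 1L
  L <- max(depths)
  levels <- lapply(seq_len(L), function(l) {
    anc <- vapply(paths, function(p) p[[min(l, length(p) - 1L) + 1L]],
                  character(1L))
    densify_ids(anc)
  })
  new_label_hierarchy(leaf_labels, levels)
}

#' Randomise a hierarchy preserving its shape
#'
#' Permutes the leaf labels uniformly at random (seeded) and re-assigns
#' them to clusters, preserving level by level the multiset of cluster
#' sizes and the nesting structure. Used by the RHCL calibration baseline:
#' random groups of the same membership sizes as the semantic groups.
#'
#' @param h a `label_hierarchy`.
#' @param seed integer seed; the same seed yields the same permutation.
#' @return a `label_hierarchy` with identical shape and permuted membership.
#' @export
random_hierarchy <- function(h, seed) {
  validate_label_hierarchy(h)
  set.seed(as.integer(seed))
  perm <- sample.int(length(h$leaves))
  levels <- lapply(h$levels, function(a) {
    b <- a
    b[perm] <- unname(a)    # leaf at position perm[i] takes leaf i's cluster
    unname(b)
  })
  new_label_hierarchy(h$leaves, levels)
}

#' Export a dendrogram or hierarchy as a Newick string
#'
#' @param x an `hclust` dendrogram or a `label_hierarchy`.
#' @param ... unused.
#' @return a Newick string (terminated by `;`) with the same leaf set;
#'   parses back with `ape::read.tree`.
#' @export
to_newick <- function(x, ...) UseMethod("to_newick")

#' @export
to_newick.hclust <- function(x, ...) {
  ape::write.tree(ape::as.phylo(x))
}

#' @export
to_newick.label_hierarchy <- function(x, ...) {
  build <- function(leaves, level) {
    if (length(leaves) == 1L && level > x$L) return(leaves)
    if (level > x$L) {
      return(paste0("(", paste(leaves, collapse = ","), ")"))
    }
    ids <- x$levels[[level]][leaves]
    groups <- split(leaves, ids)
    parts <- vapply(groups, function(g) {
      if (length(g) == 1L) g else build(g, level + 1L)
    }, character(1L))
    if (length(parts) == 1L) parts[[1L]] else
      paste0("(", paste(parts, collapse = ","), ")")
  }
  body <- build(x$leaves, 1L)
  if (!startsWith(body, "(")) body <- paste0("(", body, ")")
  paste0(body, ";")
}

#' Write a label hierarchy as JSON
#'
#' Format: `{"levels": [{"<cluster_id>": ["leaf", ...], ...}, ...]}`.
#'
#' @param h a `label_hierarchy`.
#' @param path output path.
#' @export
write_hierarchy_json <- function(h, path) {
  validate_label_hierarchy(h)
  levels <- lapply(seq_len(h$L), function(l) {
    members <- split(h$leaves, h$levels[[l]])
    stats::setNames(members, names(members))
  })
  jsonlite::write_json(list(levels = levels), path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a label hierarchy from JSON
#'
#' @param path path written by [write_hierarchy_json()] (or hand-authored in
#'   the same dialect).
#' @return a `label_hierarchy`.
#' @export
read_hierarchy_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$levels)) stop("hierarchy JSON must have a 'levels' field")
  lv <- obj$levels
  # leaf order: first appearance in the coarsest level's cluster listing
  leaves <- unname(unlist(lv[[1L]], use.names = FALSE))
  levels <- lapply(lv, function(part) {
    assign <- integer(length(leaves))
    for (k in seq_along(part)) {
      members <- unlist(part[[k]], use.names = FALSE)
      pos <- match(members, leaves)
      if (anyNA(pos)) stop("hierarchy JSON level names an unknown leaf")
      assign[pos] <- k
    }
    if (any(assign == 0L)) stop("hierarchy JSON level does not cover all leaves")
    assign
  })
  new_label_hierarchy(leaves, levels)
}
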