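test_that("embed_labels resolves tokens, averages multi-token names, errors on OOV", {
  src <- list(car = c(1, 0), pleural = c(1, 0), effusion = c(0, 1))
  expect_equal(unname(embed_labels("car", src)["car", ]), c(1, 0))
  expect_equal(unname(embed_labels("pleural_effusion", src)[1, ]),
               c(0.5, 0.5))
  expect_equal(unname(embed_labels("Pleural Effusion", src)[1, ]),
               c(0.5, 0.5))
  expect_error(embed_labels("qqqzz", src), "qqqzz")
  expect_error(embed_labels(character(0), src))
  expect_error(embed_labels(c("car", "car"), src), "unique")
  # phrase vector takes precedence over token mean
  src$pleural_effusion <- c(0, 5)
  expect_equal(unname(embed_labels("pleural_effusion", src)[1, ]), c(0, 5))
})

test_that("word2vec and JSON embedding round-trips preserve vectors", {
  tab <- random_embedding_table(5, 3, seed = 2)
  f <- tempfile(fileext = ".txt")
  write_word2vec(tab, f)
  back <- read_word2vec(f)
  expect_equal(back, tab, tolerance = 1e-12)

  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(setNames(lapply(seq_len(nrow(tab)),
                                       function(i) tab[i, ]),
                                rownames(tab)), fj, digits = NA)
  expect_equal(read_embeddings_json(fj), tab, tolerance = 1e-12)
})

test_that("build_dendrogram first merge agrees with the brute-force closest pair", {
  # three unit vectors with cosine distances d(A,B) small, d(A,C), d(B,C) large
  a <- c(1, 0, 0)
  b <- c(0.9, sqrt(1 - 0.81), 0)
  x <- 0.1; y <- (0.1 - 0.9 * x) / sqrt(1 - 0.81)
  cvec <- c(x, y, sqrt(1 - x^2 - y^2))
  tab <- rbind(A = a, B = b, C = cvec)
  # oracle: enumerate the three candidate first merges
  cosd <- function(p, q) 1 - sum(p * q) / sqrt(sum(p^2) * sum(q^2))
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  dists <- vapply(pairs, function(ij) cosd(tab[ij[1], ], tab[ij[2], ]),
                  numeric(1))
  expect_equal(which.min(dists), 1L)    # (A,B) is the closest pair
  for (linkage in c("average", "complete", "ward")) {
    dend <- build_dendrogram(tab, linkage = linkage, metric = "cosine")
    expect_setequal(dend$merge[1, ], c(-1L, -2L))
  }
})

test_that("dendrograms are valid, deterministic, and handle edge cases", {
  tab <- random_embedding_table(6, 4, seed = 3)
  d1 <- build_dendrogram(tab)
  d2 <- build_dendrogram(tab)
  expect_identical(d1, d2)
  expect_equal(nrow(d1$merge), 5L)                 # n - 1 merges
  expect_true(all(diff(d1$height) >= -1e-12))      # non-decreasing heights
  # two labels: one merge joining both
  d2lab <- build_dendrogram(tab[1:2, ])
  expect_equal(nrow(d2lab$merge), 1L)
  expect_setequal(d2lab$merge[1, ], c(-1L, -2L))
  # duplicated vectors merge first at height 0
  tab2 <- tab; tab2[2, ] <- tab2[1, ]
  ddup <- build_dendrogram(tab2)
  expect_equal(ddup$height[1], 0, tolerance = 1e-12)
  expect_setequal(ddup$merge[1, ], c(-1L, -2L))
  expect_error(build_dendrogram(tab[1, , drop = FALSE]), "at least 2")
})

test_that("cut_dendrogram produces nested levels with the requested counts", {
  tab <- random_embedding_table(10, 6, seed = 4)
  dend <- build_dendrogram(tab)
  h <- cut_dendrogram(dend, c(2, 3, 10))
  expect_s3_class(h, "label_hierarchy")
  expect_equal(vapply(1:3, n_clusters, integer(1), h = h), c(2L, 3L, 10L))
  expect_silent(validate_label_hierarchy(h))
  # identity cut: single level equal to the leaf partition
  h1 <- cut_dendrogram(dend, 10)
  expect_equal(h1$L, 1L)
  expect_equal(unname(h1$levels[[1]]), 1:10)
  # trailing repeated count duplicates the leaf-level stage
  h2 <- cut_dendrogram(dend, c(2, 10, 10))
  expect_equal(h2$levels[[2]], h2$levels[[3]])
  expect_error(cut_dendrogram(dend, c(3, 2)), "non-decreasing")
  expect_error(cut_dendrogram(dend, c(2, 11)), "exceeds")
  expect_error(cut_dendrogram(dend, c(2, 2, 5)), "end")
})

test_that("cut levels nest: every finer cluster sits inside one coarser cluster", {
  # exhaustive containment check on an 8-leaf dendrogram cut at (2, 4)
  tab <- random_embedding_table(8, 5, seed = 7)
  h <- cut_dendrogram(build_dendrogram(tab), c(2, 4))
  for (k in seq_len(n_clusters(h, 2))) {
    leaves <- h$leaves[h$levels[[2]] == k]
    parents <- unique(h$levels[[1]][leaves])
    expect_length(parents, 1)
  }
})

test_that("hierarchy invariants hold for cuts of many random embedding sets", {
  for (seed in 1:25) {
    n <- sample(4:10, 1)
    tab <- random_embedding_table(n, 4, seed = seed)
    counts <- sort(unique(c(2, sample(2:n, 2), n)))
    h <- cut_dendrogram(build_dendrogram(tab), counts)
    expect_silent(validate_label_hierarchy(h))
  }
})

test_that("hierarchy_from_edges stratifies a prior-knowledge tree by depth", {
  # flat tree: one level of singletons
  h <- hierarchy_from_edges(rbind(c("a", "root"), c("b", "root")),
                            c("a", "b"))
  expect_equal(h$L, 1L)
  expect_equal(unname(h$levels[[1]]), c(1L, 2L))
  # 2-deep tree: 6 leaves under 2 internal nodes -> levels with 2 then 6
  edges <- rbind(c("g1", "root"), c("g2", "root"),
                 c("l1", "g1"), c("l2", "g1"), c("l3", "g1"),
                 c("l4", "g2"), c("l5", "g2"), c("l6", "g2"))
  h2 <- hierarchy_from_edges(edges, paste0("l", 1:6))
  expect_equal(h2$L, 2L)
  expect_equal(unname(vapply(1:2, n_clusters, integer(1), h = h2)), c(2L, 6L))
  expect_equal(unname(h2$levels[[1]]), c(1L, 1L, 1L, 2L, 2L, 2L))
  # multi-parent node resolves to the first-listed parent with a warning
  edges3 <- rbind(edges, c("l6", "g1"))
  expect_warning(h3 <- hierarchy_from_edges(edges3, paste0("l", 1:6)),
                 "first-listed")
  expect_equal(ancestor_at_level(h3, "l6", 1), 2L)
  # cycle and orphan-leaf errors
  expect_error(hierarchy_from_edges(rbind(c("a", "b"), c("b", "a")),
                                    c("a")), "root")
  expect_error(hierarchy_from_edges(edges, c(paste0("l", 1:6), "zz")),
               "orphan")
})

test_that("uneven leaf depths stratify with shallow leaves carried down", {
  edges <- rbind(c("g1", "root"), c("deep1", "g1"), c("deep2", "g1"),
                 c("shallow", "root"))
  h <- hierarchy_from_edges(edges, c("deep1", "deep2", "shallow"))
  expect_equal(h$L, 2L)
  expect_equal(unname(h$levels[[1]]), c(1L, 1L, 2L))
  expect_equal(unname(h$levels[[2]]), c(1L, 2L, 3L))
})

test_that("random_hierarchy preserves per-level cluster-size multisets and nesting", {
  tab <- random_embedding_table(9, 4, seed = 12)
  h <- cut_dendrogram(build_dendrogram(tab), c(2, 4, 9))
  for (seed in c(1, 7, 42)) {
    rh <- random_hierarchy(h, seed)
    expect_silent(validate_label_hierarchy(rh))
    for (l in seq_len(h$L)) {
      expect_equal(sort(tabulate(rh$levels[[l]])),
                   sort(tabulate(h$levels[[l]])))
    }
  }
  expect_identical(random_hierarchy(h, 5), random_hierarchy(h, 5))
  # all-singleton levels: output equals input (dense ids relabel to identity)
  hs <- new_label_hierarchy(c("x", "y", "z"), list(1:3, 1:3))
  expect_identical(random_hierarchy(hs, 3)$levels, hs$levels)
})

test_that("ancestor_at_level agrees with a linear scan of the partition table", {
  tab <- random_embedding_table(10, 5, seed = 9)
  h <- cut_dendrogram(build_dendrogram(tab), c(2, 5, 10))
  set.seed(31)
  for (i in 1:20) {
    leaf <- sample(h$leaves, 1)
    level <- sample(h$L, 1)
    scan <- unname(h$levels[[level]][match(leaf, h$leaves)])
    expect_identical(ancestor_at_level(h, leaf, level), scan)
  }
  expect_identical(ancestor_at_level(h, h$leaves[3], h$L), 3L)
  expect_error(ancestor_at_level(h, "nope", 1), "unknown leaf")
  expect_error(ancestor_at_level(h, h$leaves[1], 4), "range")
})

test_that("to_newick round-trips through ape for dendrograms and hierarchies", {
  tab <- random_embedding_table(5, 3, seed = 21)
  dend <- build_dendrogram(tab)
  tree <- ape::read.tree(text = to_newick(dend))
  expect_setequal(tree$tip.label, rownames(tab))
  # 3-leaf topology: the first-merged pair is sisters in the tree
  a <- c(1, 0, 0); b <- c(0.95, sqrt(1 - 0.95^2), 0); cc <- c(0, 0, 1)
  d3 <- build_dendrogram(rbind(A = a, B = b, C = cc))
  t3 <- ape::read.tree(text = to_newick(d3))
  mrca_ab <- ape::getMRCA(t3, c("A", "B"))
  expect_equal(length(ape::prop.part(t3)), 2L)
  expect_setequal(ape::extract.clade(t3, mrca_ab)$tip.label, c("A", "B"))
  # hierarchy export parses back with the same leaves and grouping
  h <- cut_dendrogram(dend, c(2, 5))
  th <- ape::read.tree(text = to_newick(h))
  expect_setequal(th$tip.label, h$leaves)
})

test_that("hierarchy JSON round-trips exactly", {
  tab <- random_embedding_table(7, 4, seed = 14)
  h <- cut_dendrogram(build_dendrogram(tab), c(2, 3, 7))
  f <- tempfile(fileext = ".json")
  write_hierarchy_json(h, f)
  expect_identical(read_hierarchy_json(f), h)
})
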