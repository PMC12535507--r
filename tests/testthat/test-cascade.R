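test_that("build_stage_targets maps leaves to their ancestors per level", {
  h <- balanced_4leaf_hierarchy()
  expect_equal(build_stage_targets(h, 4L), matrix(c(2L, 4L), 1))
  # single-level hierarchy: targets pass through
  h1 <- new_label_hierarchy(letters[1:3], list(1:3))
  expect_equal(build_stage_targets(h1, c(2L, 1L, 3L))[, 1], c(2L, 1L, 3L))
  # random checks agree with per-sample ancestor_at_level calls
  tab <- random_embedding_table(9, 4, seed = 41)
  h3 <- cut_dendrogram(build_dendrogram(tab), c(2, 4, 9))
  set.seed(5)
  y <- sample(9, 30, replace = TRUE)
  tg <- build_stage_targets(h3, y)
  for (i in sample(30, 10)) for (l in 1:3) {
    expect_equal(tg[i, l], ancestor_at_level(h3, h3$leaves[y[i]], l))
  }
  expect_error(build_stage_targets(h, 5L), "outside")
})

test_that("grow_model adds stages without touching existing parameters", {
  m <- new_cascade_model(input_dim = 6, u = 4)
  m <- grow_model(m, stage_spec(1, 2, 8), seed = 1)
  expect_length(m$blocks, 1)
  expect_length(m$heads, 1)
  cs1 <- block_checksums(m)
  m2 <- grow_model(m, stage_spec(2, 3, 8), seed = 2)
  m3 <- grow_model(m2, stage_spec(3, 6, 8), seed = 3)
  expect_length(m3$blocks, 3)
  expect_length(m3$heads, 3)
  cs3 <- block_checksums(m3)
  expect_identical(cs3[["block1"]], cs1[["block1"]])
  expect_identical(cs3[["head1"]], cs1[["head1"]])
  expect_error(grow_model(m, stage_spec(3, 2, 8), seed = 1), "depth")
})

test_that("epoch-0 training is a no-op and histories have one entry per epoch", {
  fx <- fit_tiny_nscl()
  m <- fx$fit$model
  y1 <- build_stage_targets(fx$data$hierarchy, fx$data$y)[, 1]
  out <- train_stage(m, fx$data$X, y1, epochs = 0, head_idx = 1)
  expect_identical(out$model, m)
  expect_length(out$history, 0)
  out3 <- train_stage(m, fx$data$X, y1, epochs = 3, head_idx = 1, seed = 2)
  expect_length(out3$history, 3)
  expect_true(all(is.finite(out3$history)))
})

test_that("frozen scope leaves earlier blocks bit-identical; nested changes them", {
  fx <- fit_tiny_nscl()
  m <- fx$fit$model
  y2 <- build_stage_targets(fx$data$hierarchy, fx$data$y)[, 2]
  cs0 <- block_checksums(m)
  frozen <- train_stage(m, fx$data$X, y2, epochs = 2, scope = "new-only",
                        head_idx = 2, seed = 9)
  csf <- block_checksums(frozen$model)
  expect_identical(csf[["block1"]], cs0[["block1"]])
  expect_identical(csf[["head1"]], cs0[["head1"]])   # earlier head untouched
  expect_false(identical(csf[["block2"]], cs0[["block2"]]))
  nested <- train_stage(m, fx$data$X, y2, epochs = 2, scope = "all",
                        head_idx = 2, seed = 9)
  csn <- block_checksums(nested$model)
  expect_false(identical(csn[["block1"]], cs0[["block1"]]))
  expect_identical(csn[["head1"]], cs0[["head1"]])
})

test_that("training is reproducible for a fixed seed and data order", {
  fx <- fit_tiny_nscl()
  cc <- cascade_config("NSCL", widths = 16, u = 8, epochs = 3, lr = 5e-3,
                       alpha = 0.4, seed = 21)
  f1 <- train_cascade(fx$data$X, fx$data$y, cc, hierarchy = fx$data$hierarchy,
                      embeddings = fx$emb$table)
  f2 <- train_cascade(fx$data$X, fx$data$y, cc, hierarchy = fx$data$hierarchy,
                      embeddings = fx$emb$table)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$report$histories, f2$report$histories)
})

test_that("head widths follow the hierarchy's cluster counts per mechanism", {
  tab <- random_embedding_table(10, 6, seed = 50)
  h <- cut_dendrogram(build_dendrogram(tab), c(2, 3, 10))
  set.seed(1)
  X <- matrix(rnorm(40 * 5), 40)
  y <- sample(10, 40, replace = TRUE)
  nscl <- train_cascade(X, y, cascade_config("NSCL", widths = 8, u = 4,
                                             epochs = 1, seed = 1),
                        hierarchy = h)
  expect_equal(nscl$report$head_widths, c(2L, 3L, 10L))
  expect_length(nscl$model$blocks, 3)
  e2e <- train_cascade(X, y, cascade_config("E2E", widths = 8, u = 4,
                                            epochs = 1, depth = 2, seed = 1),
                       hierarchy = h)
  expect_length(e2e$model$heads, 1)           # E2E is a single stage
  expect_equal(e2e$report$head_widths, 10L)
  ncl <- train_cascade(X, y, cascade_config("NCL", widths = 8, u = 4,
                                            epochs = 1, depth = 2, seed = 1),
                       hierarchy = h)
  expect_equal(ncl$report$head_widths, c(10L, 10L))   # every stage leaf-way
  expect_error(train_cascade(X, y, cascade_config("NSCL", epochs = 1)),
               "hierarchy")
})

test_that("degenerate settings reduce mechanisms to their simpler counterparts", {
  # NSCL on a single-level hierarchy has HE2E's stage structure
  h1 <- new_label_hierarchy(letters[1:4], list(1:4))
  set.seed(2)
  X <- matrix(rnorm(30 * 4), 30)
  y <- sample(4, 30, replace = TRUE)
  nscl1 <- train_cascade(X, y, cascade_config("NSCL", widths = 6, u = 3,
                                              epochs = 1, seed = 3),
                         hierarchy = h1)
  he2e <- train_cascade(X, y, cascade_config("HE2E", widths = 6, u = 3,
                                             epochs = 1, depth = 1, seed = 3),
                        hierarchy = h1)
  expect_equal(length(nscl1$model$heads), length(he2e$model$heads))
  expect_equal(nscl1$report$head_widths, he2e$report$head_widths)
  expect_equal(nscl1$report$scopes, "all")
})

test_that("a linearly separable 2-supergroup stage trains to >= 99% accuracy", {
  cfg <- planted_config(n_super = 2, leaves_per_super = 2, u = 8,
                        delta_between = 20, delta_within = 0.5,
                        feature_dim = 8, noise_sigma = 1, n_per_class = 50,
                        seed = 13)
  ds <- simulate_classification_dataset(cfg)
  cc <- cascade_config("SCL", widths = 8, u = 8, epochs = c(15, 1),
                       lr = 5e-3, seed = 2)
  fit <- train_cascade(ds$X, ds$y, cc, hierarchy = ds$hierarchy)
  pred1 <- predict_levels(fit$model, ds$hierarchy, ds$X,
                          mode = "stage-heads")[, 1]
  truth1 <- build_stage_targets(ds$hierarchy, ds$y)[, 1]
  expect_gte(mean(pred1 == truth1), 0.99)
})

test_that("leaf prediction breaks ties toward the lowest class index", {
  m <- new_cascade_model(input_dim = 2, u = 2)
  m <- grow_model(m, stage_spec(1, 6, 2), seed = 1)
  # force identical logits across all classes: scores tie exactly
  m$heads[[1]]$P$W[] <- 0; m$heads[[1]]$P$b[] <- 1
  m$heads[[1]]$H$W[] <- 0; m$heads[[1]]$H$b[] <- 0
  out <- predict_leaf(m, matrix(rnorm(10), 5))
  expect_true(all(out$leaf == 1L))
  expect_equal(rowSums(out$scores), rep(1, 5))
  # a one-hot logit fixture predicts that class
  m$heads[[1]]$H$b <- c(-9, -9, 5, -9, -9, -9)
  expect_true(all(predict_leaf(m, matrix(rnorm(10), 5))$leaf == 3L))
})

test_that("projected-leaf level predictions are hierarchy-consistent", {
  fx <- fit_tiny_nscl()
  h <- fx$data$hierarchy
  pred <- predict_levels(fx$fit$model, h, fx$data$X, mode = "project-leaf")
  leaf <- predict_leaf(fx$fit$model, fx$data$X)$leaf
  # level-1 prediction is the predicted leaf's supergroup
  expect_equal(pred[, 1], unname(h$levels[[1]][leaf]))
  expect_equal(pred[, 2], leaf)
  # a wrong leaf in the right supergroup scores (correct, wrong)
  h4 <- balanced_4leaf_hierarchy()
  row <- build_stage_targets(h4, 2L)      # predicted leaf b, true leaf a
  truth <- build_stage_targets(h4, 1L)
  expect_equal(per_level_mismatch(row, truth)[1, ], c(0L, 1L))
  # stage-heads on a single-stage model errors
  e2e <- train_cascade(fx$data$X, fx$data$y,
                       cascade_config("E2E", widths = 8, u = 8, epochs = 1,
                                      depth = 1, seed = 1),
                       hierarchy = h)
  expect_error(predict_levels(e2e$model, h, fx$data$X, mode = "stage-heads"),
               "one head per")
})

test_that("models round-trip through the on-disk store", {
  fx <- fit_tiny_nscl()
  dir <- tempfile("model_")
  save_cascade_model(fx$fit$model, dir, report = fx$fit$report)
  back <- load_cascade_model(dir)
  expect_identical(back, fx$fit$model)
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(manifest$head_widths, fx$fit$report$head_widths)
})
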