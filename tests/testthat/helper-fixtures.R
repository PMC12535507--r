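# Shared fixture builders; everything is generated in code at test time.

random_embedding_table <- function(n, u, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * u), n, u)
  rownames(m) <- sprintf("lab%02d", seq_len(n))
  m
}

# independent severity oracle: propagate the first error downward by hand,
# then average the per-level indicators
severity_oracle <- function(mismatch) {
  first <- which(mismatch == 1L)
  if (length(first)) mismatch[first[[1L]]:length(mismatch)] <- 1L
  mean(mismatch)
}

# a hand-built 2-level hierarchy over 4 leaves: {a,b} and {c,d}
balanced_4leaf_hierarchy <- function() {
  new_label_hierarchy(c("a", "b", "c", "d"),
                      list(c(1L, 1L, 2L, 2L), 1:4))
}

# planted recovery-regime study conditions (4 supergroups x 3 leaves)
recovery_config <- function(seed = 11L) {
  planted_config(n_super = 4L, leaves_per_super = 3L, u = 16L,
                 delta_between = 20, delta_within = 1, feature_dim = 16L,
                 noise_sigma = 2, n_per_class = 200L, seed = seed)
}

# small trained cascade shared by cascade/saliency tests
fit_tiny_nscl <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- planted_config(n_super = 3L, leaves_per_super = 2L, u = 8L,
                          delta_between = 10, delta_within = 0.5,
                          feature_dim = 8L, noise_sigma = 1,
                          n_per_class = 30L, seed = 5L)
    ds <- simulate_classification_dataset(cfg)
    emb <- simulate_label_embeddings(cfg)
    cc <- cascade_config("NSCL", widths = 16L, u = 8L, epochs = 8L,
                         lr = 5e-3, alpha = 0.4, seed = 1L)
    fit <- train_cascade(ds$X, ds$y, cc, hierarchy = ds$hierarchy,
                         embeddings = emb$table)
    cache <<- list(fit = fit, data = ds, emb = emb, config = cfg)
    cache
  }
})
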