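# nscl — nested semantic cascade learning

Not all classification mistakes are equal. In medical diagnosis, confusing
two clinically similar conditions is tolerable; confusing either with a
condition needing different treatment is not. `nscl` is an R toolkit for
building classifiers whose *mistakes respect the semantics of the labels*,
and for measuring whether they do. It is aimed at researchers in
image-based and tabular multi-class inference — medical imaging
especially — who have label semantics available, either as prior knowledge
(e.g. a disease ontology) or simply as the label names themselves.

## The method

**Hierarchy construction.** Class-label names are embedded with
pre-trained word vectors (multi-token names average their token vectors),
L2-normalised, and clustered agglomeratively on cosine distance. Cutting
the dendrogram $\zeta = (\Upsilon, \Lambda)$ at a sequence of cluster
counts yields nested partitions $\Upsilon^1, \dots, \Upsilon^L$, coarse to
fine, with the deepest level the original leaf problem. Prior-knowledge
trees (e.g. a disease DAG flattened to a tree) are ingested directly and
stratified by depth.

**Cascade training.** A network grows one feature block per level. Stage
$l$ maps inputs to latents $\mathbf{R} = f_{FE}^l(\mathbf{I}) \in
\mathbb{R}^{m \times u}$ ($u$ = embedding dimension) and classifies with
$\mathbf{Y}^l = \mathrm{softmax}(f_C^l(\mathbf{R}))$ over the
$|\Upsilon^l|$ clusters of that level, minimising

$$\mathcal{L} = \alpha \cdot \tfrac{1}{m}\textstyle\sum_i
\bigl(1 - \cos(\mathbf{w}_i, \mathbf{r}_i)\bigr)
\;+\; \beta \cdot \mathcal{L}_{CCE},$$

a cosine regression of latents onto the level's class embeddings plus
class-weighted cross-entropy ($\beta = 1 - \alpha$ for $\alpha < 1$, else
$\beta = 1$). Seven mechanisms are provided: E2E, HE2E (end-to-end, the
latter with the combined loss), CL / NCL (cascade / nested cascade on the
leaf problem), SCL / NSCL (semantic: stage $l$ solves the level-$l$
problem; NSCL fine-tunes earlier blocks instead of freezing), and RHCL
(SCL on a random grouping of identical shape — the calibration baseline).

**Severity.** For each sample, predictions are compared with the truth
level by level from the root; a mismatch at any level propagates to all
deeper levels, and the severity is the fraction of mismatched levels:

$$\mathrm{severity} = \frac{L - f + 1}{L} \ \ (f = \text{first mismatched
level; } 0 \text{ if none}), \qquad X_s^{(f)} = \mathbb{E}[\mathrm{severity}].$$

Low severity means the remaining errors stay inside semantically similar
groups. Saliency masks (thresholded input gradients) are scored against
annotation masks by IOU, coverage accuracy (intersection / annotation) and
coverage precision (intersection / mask).

## Worked example

```r
library(nscl)
cfg <- planted_config(n_super = 3, leaves_per_super = 2, u = 8,
                      delta_between = 10, delta_within = 0.5,
                      feature_dim = 8, noise_sigma = 1, n_per_class = 40,
                      seed = 7)
emb   <- simulate_label_embeddings(cfg)
train <- simulate_classification_dataset(cfg, sample_seed = 1)
test  <- simulate_classification_dataset(cfg, n_per_class = 20, sample_seed = 2)

dend <- build_dendrogram(emb$table)            # cosine, average linkage
hier <- cut_dendrogram(dend, c(3, 6))
print(hier)
#> label hierarchy: 6 leaves, 2 levels (cluster counts: 3, 6 )
cat(to_newick(hier), "\n")
#> ((s1_l1,s1_l2),(s2_l1,s2_l2),(s3_l1,s3_l2));

fit <- train_cascade(train$X, train$y,
                     cascade_config("NSCL", widths = c(8, 16), u = 8,
                                    epochs = 15, lr = 5e-3, alpha = 0.4,
                                    seed = 1),
                     hierarchy = hier, embeddings = emb$table)
ev <- evaluate_model(fit$model, test$X, test$y, hier)
print(ev$severity)
#> severity report: 120 samples, 2 levels
#>   mean severity: 0.2542
#>   per-level mismatch rates: 0.108, 0.400
cat("leaf accuracy:", round(ev$leaf_accuracy, 3), "\n")
#> leaf accuracy: 0.6
```

Reading the numbers: the clustering has recovered the three planted
supergroups exactly (the Newick string groups each `s{i}`'s leaves). The
trained cascade gets 60% of the hard 6-leaf problem right, but only 10.8%
of samples are wrong at the coarse 3-group level — the mean severity of
0.254 is well below the leaf error rate of 0.400, because most mistakes
stay inside the correct supergroup and cost only the deepest level.

The same pipeline runs from a shell via the thin CLI:

```sh
exec/nscl simulate --preset tiny --seed 7 --out fx/
exec/nscl cluster  --embeddings fx/embeddings.txt --labels fx/labels.txt \
                   --counts 2,3,6 --out hierarchy.json --newick tree.nwk
exec/nscl train    --data fx/train.csv --hierarchy hierarchy.json \
                   --embeddings fx/embeddings.txt --mechanism nscl \
                   --alpha 0.4 --seed 1 --out model/
exec/nscl evaluate --model model/ --data fx/test.csv \
                   --hierarchy hierarchy.json --report report.json
```

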