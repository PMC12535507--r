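---
title: "Nested semantic cascade learning: model, metrics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested semantic cascade learning: model, metrics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nscl)
```

## The problem

In many multi-class problems — medical diagnosis from radiographs being the
motivating case — not all mistakes are equal. Confusing two clinically
similar diseases is benign; confusing either with a disease requiring a
different treatment is not. Class labels themselves carry the information
needed to tell these apart: either as prior knowledge (a disease ontology)
or through the geometry of word embeddings of the label names, where
semantically similar labels lie close together.

`nscl` operationalises this in three parts:

1. **A label hierarchy.** Label names are embedded with pre-trained word
   vectors (`embed_labels()`; multi-token names average their token
   vectors), L2-normalised, and clustered agglomeratively on cosine
   distance (`build_dendrogram()`). Cutting the dendrogram at a sequence of
   cluster counts (`cut_dendrogram()`) yields nested partitions
   coarse-to-fine — e.g. counts `(2, 3, 10)` for a ten-class natural-image
   problem. Prior-knowledge trees enter through `hierarchy_from_edges()`,
   stratified by depth.
2. **A cascade of classifiers.** `train_cascade()` grows a network one
   feature block per hierarchy level. Stage $l$ attaches an output block
   (projection to the embedding dimension $u$, ReLU, affine head, softmax)
   of width equal to the level's cluster count and trains on level-$l$
   targets. Seven mechanisms are supported: plain and hierarchical
   end-to-end (E2E, HE2E), cascade and nested cascade on the leaf problem
   (CL, NCL), their semantic counterparts (SCL, NSCL), and the random
   calibration baseline RHCL.
3. **Hierarchy-aware evaluation.** The severity of a prediction is the
   fraction of hierarchy levels, root to leaf, at which it mismatches the
   truth, with a mismatch at any level propagating to all deeper levels;
   `classifier_severity()` averages this over samples. Saliency masks from
   input gradients are scored against annotation masks by IOU, coverage
   accuracy and coverage precision.

## The loss

Each stage minimises

$$\mathcal{L} \;=\; \alpha\,\mathcal{L}_R \;+\; \beta\,\mathcal{L}_{CCE},
\qquad
\mathcal{L}_R = \frac{1}{m}\sum_{i=1}^m \bigl(1 - \cos(\mathbf{w}_i,
\mathbf{r}_i)\bigr),$$

where $\mathbf{r}_i$ is the sample's latent representation (the pre-ReLU
projection to $u$ units) and $\mathbf{w}_i$ the embedding target of its
class at the current level. $\mathcal{L}_{CCE}$ is categorical
cross-entropy, weighted per class by $N/(K n_c)$ to counter imbalance and
normalised by the applied-weight sum so the scale is comparable across
imbalance regimes. The schedule ties the weights: for $\alpha < 1$,
$\beta = 1 - \alpha$ (a convex combination); for $\alpha \ge 1$, $\beta$
is fixed at 1 and $\alpha$ alone scales the regression pull. Two points
were genuinely open and are worth recording:

* **Sign of the cosine term.** Read literally as "one minus a cosine
  *distance*", the regression term would be maximised by perfect alignment
  — a reward, not a loss. The construction this term descends from
  regresses latent vectors onto class-name embeddings by minimising
  $1 - \cos$, so that is what `cosine_alignment_loss()` computes: 0 when
  aligned, 2 when anti-aligned.
* **What supervises coarse stages.** At non-leaf levels a cluster has no
  name of its own, so no single pre-trained vector applies. The package
  uses the centroid of the member leaves' embeddings; a cluster that is a
  singleton therefore gets the leaf's own vector, and the leaf stage is
  supervised exactly as in the end-to-end hierarchical variant.

## Freeze and fine-tune contracts

Cascade-style mechanisms (CL, SCL, RHCL by default) train only the newest
feature block and the stage's output block; every earlier block is frozen
and verifiably bit-identical across the stage (`block_checksums()` hashes
each block, and the test suite asserts equality). Nested mechanisms (NCL,
NSCL) keep all feature blocks trainable. Earlier stages' output blocks
are retained but never updated after their stage, which keeps stage-wise
predictions (`predict_levels(mode = "stage-heads")`) available after
growth.

RHCL deserves a note. It is the calibration baseline: the same staged,
frozen training as SCL, but on a hierarchy whose leaf membership has been
permuted uniformly at random (`random_hierarchy()`), preserving every
level's cluster-size multiset. A nested variant (`rhcl_scope = "all"`)
exists, but empirically its leaf-stage fine-tuning largely repairs the
random grouping on the planted fixtures, converging to NSCL-like error
structure — which is why the frozen variant is both the default and the
more informative baseline.

## Severity semantics

`sample_severity()` implements propagation: the first mismatched level
forces all deeper levels to count as mismatches, so a sample whose first
error is at level $f$ of $L$ scores $(L - f + 1)/L$ and an error-free
sample scores 0. A higher severity therefore means mistakes at broader,
more consequential categories. The un-propagated mismatch fraction is
retained behind `propagate = FALSE` for diagnostics. When per-level
predictions are obtained by projecting the final leaf prediction onto its
ancestors (`predict_levels(mode = "project-leaf")`, the default for
comparisons, since it puts single-stage and cascade models on identical
footing), propagation is automatically satisfied: once ancestors differ,
all deeper ancestors differ, and the two settings provably coincide.

Confusion structure is inspected with `hierarchy_ordered_confusion()`:
leaves ordered by depth-first traversal so supergroups form contiguous
blocks, diagonal zeroed, error counts normalised and negative-log
transformed with a pseudocount (default 0.5, the Haldane–Anscombe
convention) guarding empty cells.

## The synthetic generator and what it does (and does not) show

All tests run offline on planted-structure data from `planted_config()`:

* **Label embeddings** — supergroup centres on mutually orthogonal
  directions at exact pairwise distance `delta_between`
  ($u \ge$ number of supergroups is required), leaves scattered at scale
  `delta_within`. With `delta_between/delta_within = 100` the 2-cut of the
  dendrogram recovers the planted partition with adjusted Rand index 1.
* **Classification data** — the same two-level placement in feature space,
  plus isotropic Gaussian sample noise `noise_sigma`. The study regime
  `delta_within (1) < noise_sigma (2) << delta_between (20)` with 4
  supergroups × 3 leaves and 200 samples per class makes the leaf problem
  genuinely hard while the coarse problem stays easy — exactly the setting
  in which error *placement*, not error *rate*, differentiates methods.

What passing tests on these fixtures show: the mechanics (nesting, freeze
contracts, loss identities, severity algebra) are correct, and the
directional claim — semantic grouping yields lower severity than random
grouping of the same shape at comparable accuracy — holds under planted
structure. What they do not show: behaviour on real images, where feature
hierarchies are learned rather than planted, class-conditional
distributions are far from Gaussian, and embeddings of real label names
are noisier than planted geometry. Benchmark-scale replication is out of
scope here.

## Numerical and sizing choices

* Affine (dense) feature blocks with ReLU; images are flattened, with the
  raster shape retained on the model so saliency maps reshape correctly.
  Convolutional blocks are not implemented; the staged-growth,
  freeze/fine-tune and loss machinery — the substance under test — is
  block-kind agnostic.
* Adam (the optimiser family used throughout), default learning rate
  5e-3 on the fixtures; fresh optimiser state per stage.
* The `fixture_tiny` preset uses widths (6, 32): a first stage *narrower
  than the leaf-class count* makes the coarse representation a genuine
  bottleneck, so which grouping shapes it matters — mirroring deep
  networks whose early layers are genuinely coarse. With generous early
  widths the leaf stage can compensate for a random grouping and the
  mechanisms converge. Regression weight $\alpha = 2$ (within the
  explored $[0, 7]$ range) strengthens the semantic pull.
* Probabilities are clamped at 1e-12 before logs; softmax is computed
  with row-max subtraction; ties in argmax break toward the lowest class
  index; hierarchy cluster ids are dense integers in order of first leaf
  appearance, making reports reproducible.
* One global seed expands deterministically (`derive_seed()`) into
  per-stage shuffling seeds, simulation seeds and the RHCL permutation
  seed; identical configs reproduce results bit-for-bit on fixed thread
  settings (the default single-threaded BLAS used by the test suite).
* Problem sizes in the test and acceptance runs: hierarchies up to 10
  labels (invariants checked exhaustively), training runs of ~2,400
  samples × 16 features × 2 stages, 5 seeds per mechanism — sizes at
  which every documented property is checkable in seconds to a couple of
  minutes on one CPU.

## Known limitations

* The mask threshold default (top 15% of pixels by salience) follows the
  cited benchmark's procedure in spirit; the exact fraction used there is
  not published, so it is a config knob, not a calibrated value.
* `hierarchy_from_edges()` flattens DAGs to trees by first-listed parent
  (with a warning); genuinely multi-rooted or cyclic inputs are rejected.
* Severity compares partitions level by level; it is not an LCA tree
  distance, and the two orderings can disagree on deep, unbalanced
  hierarchies.
* Very small embedding dimensions ($u <$ number of supergroups) are
  rejected by the generator since orthogonal centre placement is then
  impossible.
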