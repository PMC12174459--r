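---
title: "Methods: multi-omics graph attention with tensor fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics graph attention with tensor fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Model

`mogat` classifies patient samples into cancer stages from several omics
views measured on the same cohort. Each view is modeled by its own branch;
the branches are fused in the label space; everything is trained jointly.

**Patient graphs.** For each view, nodes are samples and edge weights are
cosine similarities between feature vectors. The graph is sparsified by
keeping the `k = round(avg_degree * n / 2)` strongest pairs (clipped to at
least one pair; ties at the threshold are all kept), which targets a mean
off-diagonal degree of `avg_degree` regardless of the similarity scale — a
fixed similarity cutoff would not transfer across datasets. Self-loops with
weight 1 are always added so every node attends at least to itself, which
also makes the attention softmax well-defined for isolated nodes. The
similarity values decide *which* pairs are neighbors; the attention
mechanism then learns *how much* each neighbor matters, so edge weights are
not otherwise consumed.

**Branches.** Three fully connected layers (ReLU, followed by per-sample
feature normalization and dropout) reduce each view to the hidden width,
then two graph attention layers aggregate over the patient graph. For edge
(i, j), the raw score is `e_ij = LeakyReLU(a^T [W h_i || W h_j])`; scores
are softmax-normalized over each node's neighborhood (with max subtraction
for overflow safety) and features update as the coefficient-weighted sum of
the neighbors' projected features, i.e. the neighbor-indexed form — the
alternative reading in which a node sums its *own* transformed feature
would make the layer independent of its neighbors and collapse it to a
gated identity map. The first attention layer uses `num_heads` heads whose
outputs concatenate; the second uses a single head followed by a linear map
to the `C` classes and a softmax. All weight matrices are Xavier-uniform
initialized (entries on ±sqrt(6/(fan_in+fan_out))).

**Fusion.** Each sample's per-view class distributions form an order-m
outer-product tensor of shape `C x ... x C`; entry `(a, b, ..., z)` is the
product of the views' probabilities for those classes, so the tensor is a
joint label distribution under a view-independence factorization and its
cells expose cross-view agreement patterns. It is flattened row-major with
view 1 as the slowest axis (fixed, so serialized fusion weights are
portable) and passed through a two-layer head (LeakyReLU, then softmax).

**Loss and training.** Every branch keeps its own cross-entropy on the
training nodes, plus `delta` times the fusion cross-entropy:
`L = sum_i L_i + delta * L_fusion`, `delta = 1` by default. Losses are
averaged (not summed) over training samples so the learning rate does not
scale with cohort size. Optimization is Adam on all parameters jointly —
the classical first-order adaptive choice for this family of models; the
branches are not pre-trained separately. Training is transductive by
default: held-out samples are present as graph nodes but contribute no
loss. An inductive mode attaches a *new* sample to its `round(avg_degree)`
most similar training nodes and runs a forward pass without rebuilding or
retraining anything; when the attachment neighborhood coincides with the
transductive graph the two modes give identical scores (this is asserted in
the test suite).

## Preprocessing

The pipeline order is fixed: quality filter → feature selection →
normalization, each *fitted on training samples only* and applied to all
samples, so no held-out information leaks into the transformations.

* **Filtering** drops features whose zero fraction or missing fraction
  exceeds `max_zero_fraction` / `max_missing_fraction` (default 0.2 each —
  the thresholds are config-exposed since no canonical values exist), then
  imputes remaining missing entries with the training-sample median
  (robust, deterministic).
* **Correlation-based selection** scores each feature by its strongest
  one-vs-rest correlation with any class,
  `score = max_c |cor(x, 1{y=c})|`, with zero-variance features scoring 0,
  and keeps `k = min(ceiling(feature_fraction * p), feature_cap)` features
  (defaults 25% and 5,000). This is a correlation *ranking* with caps, not
  a merit-based greedy subset search: the ranking form is determined by the
  caps, scales linearly in `p`, and is deterministic (ties break by feature
  name).
* **Min-max normalization** maps each feature to [0, 1] using training
  min/max, clipping applied samples into the interval; constant features
  map to 0. Normalization is per *feature*, not per sample: per-sample
  scaling would destroy the cross-sample comparability on which the cosine
  patient graph depends.
* **Methylation renaming** replaces CpG-site identifiers with adjacent-gene
  names from a two-column mapping table; unmapped sites are dropped, and
  when several sites map to one gene the highest-variance site wins
  (logged).

## Evaluation protocol and metrics

`run_experiment()` draws `num_repeats` (default 10) stratified splits with
`train_fraction` 0.7 — stratification uses largest-remainder allocation so
the train size hits `round(0.7 n)` exactly and no class can vanish from
either partition — then refits preprocessing, graphs and model per repeat
and scores the held-out samples. Repeat r uses seed `seed + r`; identical
seeds reproduce results bitwise.

Metrics are computed from the multiclass confusion matrix: accuracy
(trace over total), weighted recall (support-weighted per-class recall —
algebraically equal to accuracy for single-label predictions, an identity
the tests assert), per-class F1 (harmonic mean of precision and recall,
0 when both vanish), macro F1 (unweighted mean over all `C` classes, absent
classes contributing 0) and weighted F1. Predicted classes are argmax with
ties broken toward the lowest class code.

Ablations are driven by configuration: `views` restricts to any of the
`2^m − 1` omics combinations (`view_combinations()` enumerates them) and
`use_vcdn = FALSE` bypasses the fusion head, averaging the branch
distributions instead — also the rule for single-view runs, where there is
nothing to fuse.

## Biomarker ranking

Graph attention weights live on patient–patient edges, not on features, so
"feature importance" needs an operational definition. The primary one is
masking/ablation importance: a feature's importance is the drop in held-out
weighted F1 when its column is replaced by zeros while the trained
parameters and the patient graph stay fixed. Zero is the post-min-max
floor, so masked inputs stay in-domain (mean-masking would instead create
values the model may never have seen in that column's role). Importance is
computed on the held-out partition only, so overfit features are not
rewarded; features never selected into the model score exactly 0. A
gradient-times-input score (`method = "gradient"`, mean of `|x * dL/dx|`
over held-out samples) is available as a secondary view and is reported as
such, never silently substituted. Stage-pair tables re-run the entire
pipeline on each adjacent-stage binary task, mirroring the way
transition-specific markers are isolated; whether ranking should use the
multiclass model or per-pair models is under-determined, and per-pair was
chosen because it matches the per-transition reporting structure.

A structural caveat the package's own validation surfaced: ablation
importance is only identifiable when each planted feature individually
matters. If a model sits at 100% held-out accuracy on top of many mutually
redundant informative features, masking any single one flips no prediction
and every drop is exactly 0 — true for *any* ablation-style method, not a
defect of this one. The biomarker validation scenarios below are therefore
designed with per-feature-identifiable signal.

## Synthetic data

The generator stands in for normalized multi-omics stage cohorts and is the
package's test surface. It emulates: several views of differing
dimensionality; per-class mean-shifted informative features (class `c`
drawn `Normal(c * effect * d_j, noise_sd)` with a fixed random sign `d_j`);
view-specific Gaussian noise; a methylation-like view pushed through the
logistic function so values resemble beta-values, strictly inside (0, 1);
balanced stages named I, II, …; and seeded per-view substreams, so adding a
view never changes earlier views' draws. A Gaussian class-shift model is
the right level of realism here because the pipeline consumes
already-normalized [0, 1] values — count noise, batch effects and
library-size artifacts live upstream of this package's contract, and the
generator makes no attempt to imitate read counts, CpG coordinates or
cohort barcode semantics. Passing tests therefore demonstrate correctness
of the method's mechanics and its behavior under controlled signal, not
performance on real cohorts.

Two optional structures support specific validations:

* `shared_latent = TRUE` splits the class into a coarse and a fine
  partition (view 1 sees `c mod ceiling(C/2)`, view 2 sees
  `c %/% ceiling(C/2)`, further views carry no signal), so no single view
  can identify the class while two views together can — by construction the
  single-view Bayes ceiling sits strictly below the two-view ceiling (the
  tests verify this with a brute-force Bayes rule on the generating model).
  This is the regime where label-space fusion provably must beat every
  single branch.
* `pair_boundary = t` plants one step feature whose mean jumps by
  `pair_effect` between classes below and from `t`, so exactly one adjacent
  stage pair sees its signal — ground truth for stage-pair specificity.

## Validation scenarios and problem sizes

The acceptance-style tests run, at the default hyperparameters:

* *Planted signal*: n = 300, C = 3, three views, 10 informative features
  per view at `effect = 3`, 10 repeats — mean held-out accuracy must reach
  0.90; with `effect = 0` the mean must sit within three standard errors of
  1/3.
* *Fusion ablation*: n = 300, C = 4, two complementary shared-latent views;
  the fused model's mean accuracy must strictly beat the best single view.
* *Biomarker recovery*: a single expression view (p = 50, s = 5,
  `effect = 1.5`), chosen so the model is good but unsaturated (~85–90%
  accuracy) and every planted feature carries weight it cannot replace —
  see the identifiability caveat above; planted features must be recovered
  in the top-2s with recall ≥ 0.8 over 10 seeds. The stage-pair scenario
  uses three views with weak regular signal (`effect = 1`, s = 5) plus one
  step feature at `pair_effect = 4`, which must surface in its own pair's
  top 3 and no other's in at least 7 of 10 seeds.

These sizes keep the full suite within a few minutes on a single CPU while
leaving each check a comfortable margin; they are the package's validation
conditions, stated here so they can be revisited deliberately rather than
drifting.

## Numerical choices

* LeakyReLU negative slope 0.2 everywhere (the standard graph-attention
  constant); ELU on the hidden attention layer, identity before the final
  softmax.
* "Normalization layer" after each fully connected layer = per-sample
  feature standardization (batch-size independent, epsilon 1e-5), plus
  dropout 0.5 — both config-exposed (`use_layernorm`, `dropout`) since
  neither the type nor the placement is canonical.
* Softmax always with max subtraction; cross-entropy probabilities floored
  at 1e-12 for finiteness.
* Adam with beta1 0.9, beta2 0.999, epsilon 1e-8; non-finite loss aborts
  with the offending epoch.
* Branch depth is fixed at two attention layers (one concatenating
  multi-head layer, one single-head output layer): the first mixes the
  neighborhood in a rich multi-head representation, the second distills it
  for the class head, and deeper stacks over-smooth on graphs of a few
  hundred patients. The class head always maps to `C` classes.
* Zero-length sample vectors get cosine similarity 0 to everything;
  negative similarities are treated as no affinity.
* All tie-breaks are deterministic: argmax to the lowest class code,
  feature rankings by name, stage order lexicographic (which orders Roman
  numerals I–V correctly) or by factor levels when provided.
* Gradients are validated against central finite differences at a generic
  parameter point (random biases). At the exact ReLU kink created by
  zero-initialized biases the subgradient convention (derivative 0 at 0)
  differs from a one-sided numerical slope amplified by the normalization
  layer; this is the usual autodiff convention, not an implementation
  error, and disappears after the first optimizer step.

## Limitations

* Real-cohort performance is out of scope: the package ships no cohort
  downloader, and accuracy on real cohorts cannot be inferred from the
  synthetic validation.
* The generator's Gaussian, feature-independent noise understates the
  correlation structure of real omics; graphs built from it are easier
  than real patient-similarity networks.
* Ablation importance underestimates mutually redundant biomarkers (see
  above); the gradient-based score shares the limitation in milder form.
* Training is full-batch; cohorts beyond a few thousand samples would need
  a different optimization regime than the one tuned here.
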