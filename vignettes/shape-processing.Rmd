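---
title: "Probing 3D shape representations in point-cloud classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing 3D shape representations in point-cloud classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapecloud)
```

## The scientific question

Humans recognise objects from point clouds — sparse, textureless sets of
points sampled from an object's surface — with striking robustness: thinning
the points, turning the object upside down, or quantising its surface into
voxel blocks barely dents recognition, while breaking the *configuration* of
an object's parts is devastating. Deep point-cloud classifiers reach
human-level accuracy on intact objects, but whether they carry human-like
*global shape* representations is a different question, and it can be probed
behaviourally: perturb the stimuli along dimensions that dissociate local
geometry from global configuration, and compare the accuracy patterns and
confusion structure of models against human observers.

`shapecloud` implements that entire pipeline in R:

* a procedural generator of part-annotated 3D objects (so the pipeline is
  testable without the external CAD datasets),
* the stimulus perturbations — density downsampling, inversion, voxel
  ("Lego") deformation, part scrambling,
* two classifier families built and trained from scratch — DGCNN
  (dynamic-graph edge convolution) and the Point Transformer (vector
  self-attention with progressive downsampling) — plus composable ablations
  and an architectural intervention,
* the behavioural-comparison statistics: confusion matrices, off-diagonal
  confusion correlations, pooled accuracy-pattern correlations, and
  Steiger's test for dependent correlations.

## The models

Both families consume an N x 3 cloud in a unit-sphere frame (y vertical)
and emit class logits.

**DGCNN.** Each EdgeConv stage builds, for every point i and each of its
k = 20 nearest neighbours j *in feature space*, the edge feature
$(f_j - f_i,\, f_i)$, maps it through a shared linear layer + batch norm +
leaky ReLU, and aggregates by a channel-wise maximum. Because neighbourhoods
are recomputed from features at every stage, the graph is "dynamic".
Stage outputs (widths 64/64/128/256) are concatenated, embedded to 1024
channels, max- and mean-pooled over points, and classified by a 512/256
head with batch norm and dropout. The default build has 1,809,576
trainable parameters (1.81M).

**Point Transformer.** Points are embedded (3 → 32 → 32) and processed by
vector self-attention blocks: with neighbours defined by k = 16 nearest
points in 3D space, the attention input for pair (i, j) is
$q_i - k_j + \delta_{ij}$, where $\delta_{ij}$ is a learned *position
encoding* of the relative displacement $x_i - x_j$; a two-layer MLP turns
this into a per-neighbour attention *vector* (one weight per channel),
softmax-normalised over the k neighbours, and the output is
$\sum_j a_{ij} \odot (v_j + \delta_{ij})$ with a residual connection.
Between blocks, *Transition Down* stages reduce the point count at the
fixed ratio schedule $[N, N/4, N/16, N/64, N/256]$: representatives are
chosen by farthest point sampling and each aggregates its k nearest source
points through a small MLP with a channel-wise maximum, doubling the width
(32 → 64 → 128 → 256 → 512). Global mean pooling and a 256/64 head close
the network: 9,584,040 trainable parameters (9.58M). The schedule's N is
the *nominal* cloud size the model is configured for (`n_points` in the
spec), so the absolute target counts are fixed and merely clamped to the
points available at run time: feeding a thinned cloud does not shrink the
deep abstraction stages — which is exactly the property that makes
hierarchical downsampling a density-robustness mechanism rather than a
liability.

**Ablations and intervention.** `ablate()` removes exactly one mechanism
from the Point Transformer: `NoAttn` replaces the learned attention weights
by a uniform mean over the value terms; `NoPE` sets the positional term to
zero everywhere; `NoDS` keeps every Transition Down stage at full
resolution (local re-embedding without reduction, leaving the parameter
count untouched — the reduction itself has no parameters).
`add_downsampling_to_dgcnn()` inserts a Transition Down stage (ratio 4)
after every EdgeConv layer; subsequent feature graphs are computed on the
reduced set. With downsampling the multi-scale concatenation uses each
stage's post-reduction features at the surviving points (tracked through
the chain of farthest-point selections), so every stage stays on the
gradient path.

Two reference formulations are deliberately pinned by the published
parameter counts: the DGCNN head consumes concatenated max *and* mean
pooling (2048 inputs), and every attention block shares the inner width
d_model = 512. Where fewer neighbours than k exist (deeply downsampled
stages, sparse stimuli), the effective neighbourhood is `min(k, M)`: padding
by repetition would duplicate rows and degenerate the normalisation
statistics.

## Training

Training follows the published protocol: Adam at 0.001 with a step
schedule (x 0.3 every 50 epochs), cross-entropy loss, and per-cloud
augmentation in the order dropout → scale → shift. Dropout draws a ratio
uniformly from [0, 0.875] and replaces `floor(ratio * N)` randomly chosen
points by the *first point's coordinates* (the cloud never loses points);
scale is uniform in [0.8, 1.25]; the shift is per-axis uniform in
[-0.1, 0.1]. Minibatches are processed in lockstep — the clouds are
concatenated row-wise, sharing every linear/batch-norm step while graph
operations stay block-diagonal per cloud — so batch norm normalises over
the whole minibatch during training and uses running averages in
evaluation. All forward *and* backward passes are hand-implemented on
BLAS matrix operations and validated against central-difference numerical
gradients in the test suite.

## The synthetic shape generator

The generator emulates the statistical structure the experiments assume,
not any particular CAD repository: ≥ 10 nameable categories (airplane,
bottle, bowl, chair, cup, lamp, person, piano, stool, table, plus a car
for the scrambling pool), each assembled from parametric primitives (boxes,
cylinders, cones, sphere caps/bands, torus segments) grouped into 3–12
semantically coherent parts. Surface sampling is area-uniform: a primitive
is selected with probability proportional to its analytic surface area,
then a point is placed uniformly on that surface with the appropriate
area-preserving corrections (e.g. minor-angle rejection sampling on tori).
Within-category instance variation comes from jittering every size
parameter uniformly within ±20% of its default, driven by the instance
seed; the magnitude is a stand-in for the unmodelled variability of real
CAD instances, chosen once. Clouds are unit-sphere normalized, default
1,024 points (256 in the desk profile).

What the generator does *not* emulate: mesh topology, texture, non-rigid
within-category deformation, or the long-tailed instance diversity of real
object repositories. Passing tests therefore demonstrate that the pipeline
and the architectural contrasts behave as designed under controlled
conditions — not that any model matches human vision on real stimuli.

```{r generator, eval = FALSE}
tpls <- shape_templates(scramble_categories())
ds <- generate_dataset(tpls, n_train_per_cat = 16, n_test_per_cat = 6,
                       seed = 101, n_points = 256)
ds
```

## Stimulus perturbations

* `downsample_density(pc, p, seed)` keeps a uniformly random subset of
  `floor(p * N)` points (minimum 1); the printed density grid is 20–100%.
* `invert(pc)` is a proper 180° rotation about the horizontal x axis,
  `(x, y, z) -> (x, -y, -z)` — an involution and an isometry.
* `voxelize_lego(pc, v, seed)` builds the occupancy grid at voxel size `v`
  (origin anchored at the bounding-box minimum), enumerates *exposed* voxel
  faces (interior faces are invisible in rendered stimuli), samples the
  output area-uniformly over those faces, and renormalizes. Voxel sizes
  0.01–0.2 (unit-sphere units) span the printed deformation range;
  `v = 0` denotes the intact condition.
* `subdivide_large_parts()` splits any part holding more than 30% of the
  cloud into 3 spectral clusters (symmetric k = 10 nearest-neighbour
  affinity graph, normalized Laplacian embedding, k-means).
* `scramble_parts()` picks an anchor part uniformly at random, centres it
  at the origin, centres every other part on its own centroid and offsets
  it by a uniform draw from the cube `[-r, r]^3` with r = 0.6, then
  renormalizes globally — so each part's internal geometry survives up to
  one shared scale.

Every randomized transform is a pure function of its seed, and experiment
runners record that seed per row, so any stimulus can be regenerated
exactly from the predictions table.

## Experiment designs and behavioural statistics

`design_exp1()` crosses the seven density proportions with
upright/inverted over the ten experiment categories (7 test instances per
category: 490 stimuli per orientation, 980 model-test rows);
`design_exp2()` runs the five voxel levels (including intact);
`design_exp2_participant()` enumerates one participant's 40-trial Lego
session. `build_exp3_stimuli()` reproduces the scramble selection rule:
per source model, 10 originals per category from the five-category pool,
each paired with a scramble the model labels identically to its original
(regenerating with fresh seeds up to a retry cap) — 200 stimuli across two
source models.

On the analysis side, `offdiag_correlation()` row-normalises two confusion
matrices, discards the diagonal, and correlates the remaining
misclassification cells (row-normalisation is the default because raw
counts would confound unequal trial totals between humans and models;
`normalize = FALSE` exposes the raw mode). `accuracy_pattern_correlation()`
correlates condition-wise accuracies of aligned profiles, and
`compare_dependent_correlations()` implements Steiger's (1980) Z for two
correlations sharing one variable (the human profile), with the pooled-r
covariance estimate — z < 0 when the first correlation is smaller. Human
data enter only as delimited text tables (`load_human_table()`); nothing
in the package requires them.

## Numerical choices and degenerate inputs

* Unit-sphere normalization of a degenerate (single-point or coincident)
  cloud centres it and leaves the scale at 1.
* Subset sizes use `floor(p * N)` with a minimum of 1 (so 20% of 1024 is
  204); the dropout count uses the same floor rule.
* kNN ties break to the lowest index; farthest point sampling starts, by
  default, at the point farthest from the centroid (a deterministic choice
  that also makes the selected set independent of point order) and breaks
  ties to the lowest index; argmax ties in pooling take the first maximum.
* Batch-norm eps is 1e-5; running statistics use momentum 0.1.
* Spectral clustering uses the symmetric normalized Laplacian with
  row-normalised eigenvectors and `stats::kmeans` (10 restarts, seeded).
* Points exactly on a shared voxel boundary belong to the upper cell.

## The desk-scale profile

The full protocol (40 CAD categories, 1,024-point clouds, 200 epochs) is
far beyond a CPU session, so `desk_profile()` pins a reduced study:
256-point clouds, width-reduced specs (DGCNN 16/16/32 with k = 10; Point
Transformer base width 8, d_model 32, k = 8, three Transition Down stages
so the deepest stage keeps ≥ 4 points at the nominal size — a single-point
stage gives normalisation statistics no support), batch 8, and short Adam
training. The replication suite trains this profile on the ten experiment
categories (10 train / 4 test instances each, 15 epochs, ~5 min per seed
on one CPU) across three seeds and checks the *orderings* the full-scale
study reports: the no-downsampling Point Transformer degrades more than
the original when density drops to 20%; DGCNN with Transition Down beats
plain DGCNN at 20% density; and part-scrambled stimuli are recognised
worse than intact ones by both families. Absolute accuracies at this
scale are not comparable to the published ones and are not asserted.

## Known limitations

* Synthetic categories are far more geometrically regular than real CAD
  models; absolute accuracies saturate quickly and generalisation gaps are
  driven mostly by the size jitter.
* Training determinism holds for a fixed seed on a fixed BLAS build;
  different BLAS libraries may reorder floating-point reductions.
* The NoAttn and NoPE substitutions are one defensible reading of
  "removing" those mechanisms (uniform neighbour weighting; zero positional
  term); alternatives are easy to plug in behind `ablate()`.
* Full-scale replication of the published accuracies requires the external
  datasets and GPU-scale training and is out of scope for the shipped
  profile.
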