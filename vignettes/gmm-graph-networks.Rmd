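---
title: "GMM-filter graph convolutions on superpixel graphs: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GMM-filter graph convolutions on superpixel graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gmmconv)
```

This vignette is the package's own account of the method it implements: the
model and its assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, the numerical choices, and the known
limitations. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. From image to graph

A grayscale image in [0, 1] is partitioned into superpixels by SLIC with a
requested segment count of `round(H*W / A)`, where `A` is the expected
average superpixel area in pixels². SLIC is implemented in compiled code
inside the package (no installed R package provides it): grid-initialized
windowed k-means over (intensity, x, y), ten iterations, followed by
connectivity enforcement that absorbs fragments smaller than a quarter of
the expected area into an adjacent segment and relabels contiguously.
Intensity is scaled by 100 in the distance metric so the conventional
compactness default of 10 balances color against space the way it does for
a luminance channel in [0, 100]; the result on smooth images is a compact,
boundary-following partition, and on constant images a near-regular grid.

The graph has one node per superpixel with its mean intensity as the single
input feature. Two superpixels are 1-hop adjacent when they share a pixel
boundary under 4-connectivity — the most conservative notion of "spatial
adjacency". The directed edge set contains every ordered pair within hop
distance `D`, plus a loop on every node so a node's own feature reaches its
own output. Edge pseudo-coordinates are centroid offsets in a y-up frame
(pixel rows grow downward, so the row difference is negated), divided by
`coord_scale = D*sqrt(A)`. Two consequences drove this convention:

* angles follow the counterclockwise mathematical convention, so "rotate by
  θ" means the same thing for filters, for edges and for `atan2`;
* the farthest reachable neighbours sit near magnitude 1, so Gaussian means
  initialized in [−1, 1]² cover the whole receptive field and variances of
  1 are a sensible starting width.

Targets, when a binary mask is supplied, are `W` times the mask coverage
fraction of each superpixel, hence in [0, W] and fractional along the mask
boundary. `W = 100` (the default) inflates the regression signal enough
that full-batch MSE training does not settle into the all-zero response; it
has no effect on detection itself, which only ranks nodes.

Masks are downscaled by nearest-neighbour (values must stay binary), images
bilinearly. The default `downscale` is 1 in this package because the
synthetic scenes are already small; for large photographs 0.25 is the
natural choice and is exposed in `graph_config()`.

## 2. The convolution and its parameter count

A layer computes, per output channel m and node s,
`h_m(s) = Ψ(b_m + Σ_n Σ_{t∈N(s)} φ_{n,m}(u(s,t)) f_n(t))`, with an
independent trainable filter per (input, output) channel pair, and each
filter a J-component Gaussian mixture with scalar weights, 2-D means, and
diagonal covariances — J(2d+1) scalars per filter at d = 2. The per-layer
trainable count is MN(J(2d+1)+1): the "+1" assigns one bias scalar to each
filter. The effective bias of channel m in the layer equation is then the
sum of the biases of its N filters. Functionally this is just an
overparameterized per-channel bias (all N scalars receive identical
gradients), but it keeps the stored parameter enumeration equal to the
closed-form count — 420 for the 2-layer verification network, 5775 for the
4-layer main network — which the tests assert by enumeration.

Numerical details that matter:

* **Variance positivity.** Variances are stored as log-variances and
  exponentiated at evaluation; optimization is unconstrained and positivity
  is structural. `gmm_filter()` (the user-facing single-filter object)
  validates positive variances at construction instead.
* **Deterministic accumulation.** Edges are sorted by (s, t) and the
  compiled forward/backward loops run in a fixed order, so repeated runs
  are bit-identical.
* **Exact-zero features.** The kernels skip contributions where the input
  feature is exactly 0. Forward this is algebraically exact; backward it
  drops only the feature-gradient of zero features, which is provably
  unused: hidden zeros arise from ReLU (whose subgradient at a clamped unit
  is 0 here) and first-layer inputs receive no gradient. The finite-
  difference test covers every stored parameter and confirms agreement to
  better than 1e-4 relative.
* **Activations.** Only ReLU and identity are used (identity on the last
  layer); the registry is a two-entry map and adding activations means
  adding a code and its derivative to the compiled kernel.

## 3. Initialization

The scheme is Glorot-uniform on the mixture weights with `fan_in = N*J` and
`fan_out = M*J`, means uniform in [−1, 1]² (one normalized hop, see §1),
log-variances 0, biases 0. The reference libraries differ in which GMM
parameters the "Glorot scheme" governs and their defaults changed across
versions; this package's choice keeps initial layer responses O(1) over the
unit-scaled pseudo-coordinate range and is deterministic given a seed.

## 4. Training protocol

MSE loss over nodes (per-graph node-mean, averaged over graphs) and Adam
(β₁ = 0.9, β₂ = 0.999, ε = 1e-8 — standard defaults; only the learning
rate is treated as a protocol parameter: 1e-3 for the oriented-edge task,
1e-4 for detection). Every 50 steps the train and validation errors are
recorded and the final model is the recorded checkpoint with minimal
validation error; this guards against overfitting and makes "the trained
network" well defined. Model selection uses validation MSE, not validation
detection accuracy: MSE is the trained objective and accuracy at desk scale
is too coarse (steps of 1/30) to rank checkpoints.

Batching: the default step is full-batch over all training graphs —
deterministic and appropriate for the 60-graph verification task, where
2000 full-batch steps take well under a minute. For the 150-scene detection
task the same 2000-step budget is run on mini-batches of 8 graphs (sampled
without replacement, reshuffled each pass, seeded): the Adam step count and
learning-rate regime are preserved while each step touches ~9% of the
edges, which keeps the experiment at a few minutes on one CPU. Graphs are
merged into a disjoint union per step so each step is a single
forward/backward pass.

"Epochs" and "steps" coincide for full batch; the history's epoch column
counts optimizer steps in both modes.

## 5. Rotation and mirroring

`φθ(u) = φ(R(−θ)u)` is implemented by composing a 2×2 orthogonal transform
applied to edge pseudo-coordinates at evaluation time, not by materializing
rotated means and covariances. This is exact (the algebraic identity
`φθ(R(θ)u) = φ(u)` holds to floating point, asserted at 1e-9 over random
networks and graphs), keeps the diagonal-covariance storage invariant (a
rotated anisotropic Gaussian generally has a full covariance), makes
rotations compose additively and invert trivially, and costs nothing per
network. The mirror transform is the same mechanism with `diag(-1, 1)`.

The rotation bank for `count = 11` uses angles `seq(-pi, pi, length.out =
11)` — spacing π/5, zero included, both endpoints present. −π and π
coincide modulo 2π, so the bank nominally evaluates one angle twice; since
a rotated network shares all parameters with its base and differs only by
the 2×2 transform, deduplication would save one graph evaluation per image
at the cost of an 11-member bank not having 11 members. The package keeps
all 11. Serialized banks store the base checkpoint once plus the angle
list.

Decision rules: "max" picks the (network, node) pair with the globally
largest output (ties: smaller |angle|, then smaller angle, then lower node
id); "any" accepts when at least one bank member's argmax is a hit. By
construction any-rule accuracy dominates both the max rule and the single
unrotated network; the max rule can fall below the single network because
rotated copies contribute spurious maxima in texture regions.

## 6. Oriented-edge soft labels

The verification task labels each node with
`hθ(s) = max(Σ ωθ²(s,t)(f(t)−f(s)) / Σ ωθ²(s,t), 0)` over neighbours with
positive orientation weight `ωθ(s,t) = sin(α(s,t) − θ)`, α being the edge
angle in the y-up convention. The weight is written as a function of the
edge (s, t); loops are excluded (their angle is undefined), and a node with
no positively weighted neighbour gets 0 — its normalizer would be 0/0 and
the max(·, 0) semantics make 0 the natural value. Under this convention
θ = 0 marks nodes whose upward neighbours are brighter (the lower outer
boundary of a bright blob); θ and θ+π mark opposite sides, and rotating a
graph's pseudo-coordinates by δ shifts the detected orientation by exactly
δ — both properties are asserted in the tests.

## 7. What the synthetic generator emulates — and what it does not

The generator stands in for a profile-image ear dataset with per-image
binary masks. It reproduces the *structural* properties the method depends
on: exactly one connected target region per image; a large, brighter
head-like region whose boundary carries the target; background variation
(flat, gradient, and smoothed-noise textures), per-scene illumination
scaling, and pixel noise; in-plane rotation of the target about its own
centre; subject identity (appearance parameters fixed per subject) enabling
person-disjoint splits in the 75:25:26 proportions of a 126-person cohort.
Scenes default to 96×128 px so that ~48 superpixels at A = 256 cover them
and a full train/evaluate cycle runs in minutes on one CPU; the target is
kept ≥ 20 px from the frame border by default (border placement is a known
failure mode of bounding-box detection and can be enabled deliberately for
negative tests via `border_margin`).

It does **not** emulate photorealism: no occlusion, no motion blur, no
out-of-plane pose change, no annotation noise, and the target is by
construction the brightest compact structure, which makes the synthetic
task considerably easier than real biometric imagery. Passing tests
therefore demonstrate that the pipeline, the gradients, the equivariance
algebra and the decision rules behave as specified — not that the
architecture reaches any particular accuracy on real photographs. Absolute
accuracies on real datasets are outside what this package can reproduce
without that data.

The blob-mask generator (verification task) draws star-shaped regions with
smooth harmonic boundaries, jittered centres and 10–40% area fraction —
connected by construction and matching the granularity at which A = 400
superpixel graphs have a few tens of nodes.

## 8. Detection and evaluation

Detection is argmax over the final-layer node outputs (ties broken by the
lowest node id, documented and asserted); the hit criterion is the argmax
superpixel's centroid falling inside the ground-truth bounding box enlarged
by √A pixels per side (boundary inclusive). The enlargement absorbs the
fact that a superpixel's centroid can sit up to about one superpixel
diameter outside the tight box while the superpixel itself overlaps the
target; it is configurable.

## 9. Problem sizes and run times

The shipped experiments are sized for a desk machine: the verification
experiment uses 100 masks of 96×128 px (graphs of ~30 nodes, D = 1),
trains 2000 full-batch steps in well under a minute, and evaluates six
base-vs-rotated comparisons; the detection experiment uses 150 scenes
(~48 nodes each, D = 2, ~700 edges per graph), 2000 mini-batch steps, and
an 11-network bank over 30 rotated test scenes, for a few minutes total.
Memory stays in the tens of megabytes (the largest transient is the cached
Gaussian evaluations of one mini-batch).

## 10. Known limitations

* Single input channel (mean intensity); color or multi-channel features
  are out of scope.
* SLIC is the only segmentation backend.
* The SLIC distance scaling (intensity ×100) makes segmentation of
  *unstructured high-frequency noise* degenerate toward intensity
  clustering; realistic images are unaffected, but pathological inputs can
  yield far fewer superpixels than requested.
* No downsampling/upsampling blocks: the reduced graph representation is
  the mechanism that keeps parameter counts small, and the architecture
  relies on it.
* Rotation equivariance is exact for the *filters*; the superpixel
  partition itself is not rotation-covariant (SLIC on a rotated image does
  not produce the rotated partition), so end-to-end equivariance on pixels
  is approximate even though it is exact on graphs.
* Training is CPU-bound single-threaded; the package targets small graphs
  (hundreds of nodes), not large-scale batched GPU workloads.
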