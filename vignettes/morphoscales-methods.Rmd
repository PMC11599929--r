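---
title: "Multi-scale neuron morphometry: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale neuron morphometry: models, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoscales)
```

# Scope and data model

`morphoscales` analyzes neuronal anatomy at five nested scales —
region-level neurite co-occurrence, dendritic microenvironments,
single-cell full morphology, sub-neuronal arbors and tracts, and axonal
varicosities — plus the cross-scale diversity/stereotypy summaries that tie
them together. The central container is the `neuron_tree`: a rooted SWC
morphology with coordinates in micrometres in the CCF frame (x
anterior-posterior, y dorsal-ventral, z left-right), per-node radii, and
structure labels (soma = 1, axon = 2, basal = 3, apical = 4). Voxel-based
parameters always travel with an explicit voxel size; a single canonical
unit (um) avoids the voxel/um ambiguity that plagues mixed imaging
pipelines.

A reconstruction is considered analyzable when it passes six structural
criteria (`validate()`): a single soma, a single connected component, no
cycles, no duplicated compartments, bifurcation-only branching outside the
soma, and consistent dendrite/axon labels along each branch. Files with
multi-point somas are collapsed to the first soma node (children
re-parented), which is the dominant community convention; the collapse is
reported with a warning because it is a convention, not a property of the
data.

# Morphometric features

Global features follow the Vaa3D flavor of L-Measure: coordinate spans are
full (untrimmed) ranges; `Surface` and `Volume` treat each parent-child
segment as a conical frustum; `AverageContraction` is the per-branch
Euclid/path ratio averaged over branches; `AverageFragmentation` is pinned
as compartments (edges) per branch, since the exact Vaa3D counting is not
documented. `HausdorffDimension` is a box-counting estimate: eight dyadic
box sizes descending from (bounding-box diagonal)/4, boxes anchored at the
bounding-box corner, and the least-squares slope of log N(s) against
log(1/s). The estimator is pinned in full detail so results are exactly
reproducible; box counting over node coordinates underestimates the
dimension of very sparsely sampled cable, which is acceptable because the
feature is only ever used comparatively.

Per-branch features attach angle information to the branch's *distal*
bifurcation (terminal branches carry defined zeros): amplitude is the angle
between the two child directions, tilt the mean angle between each child
direction and the direction back toward the soma. "Local" variants use the
immediate child compartments, "remote" variants the vectors to the next
topological points. Tilt as the mean of the two parent-child angles is
symmetric and stable; a min-angle variant would be noisier under tortuosity.
Partition asymmetry is `|n1 - n2| / (n1 + n2 - 2)` over subtree tip counts
(0 when both children are tips); note that any `(n, 1)` split scores exactly
1 under this standard formula.

The 47-dim full-morphology vector is 7 globals (Stems, Branches,
OverallWidth/Height/Depth, OverallVolume — an alias of the frustum Volume,
the only volume feature in the set — and Length) plus min/max/mean/SD of
the 10 branch features. Standard deviations are population SDs (divisor
n), chosen so that single-branch trees yield exact zeros rather than NA.
The 24-dim local-dendrite vector drops Nodes, SomaSurface, AverageDiameter
and Surface from the 22 globals and appends six PCA shape features: the
explained-variance shares of the three principal axes of the node cloud
(summing to 1) and the first axis normalized to unit absolute sum, sign
fixed so its largest component is positive.

# Dendritic microenvironments

A microenvironment fuses a target neuron with up to five neighbors inside a
sphere of radius `D`. Candidacy is purely spatial (soma distance at most
`D`); ranking among candidates is morphological — Euclidean distance
between 24-dim vectors z-scored over the whole analyzed population.
Population-level z-scoring is the only internally consistent choice: a
per-microenvironment scope would make neighbor ranking depend on the
candidate set itself. `D` defaults to 249 um, the median 5th-nearest-
neighbor soma distance of the whole-brain dendrite population this
representation was designed around; `calibrate_radius()` recomputes it for
any population. Fusion weights are `exp(-d_i/D)` normalized to sum to one,
so the fused vector is a convex per-coordinate combination of the member
vectors; with no neighbors it is exactly the target's vector.

mRMR feature selection uses the MID (difference) scheme with mutual
information on 3-bin discretized features (bins at mean +/- SD). Columns
with at most three distinct values are used as-is: forcing the Gaussian
bins onto a binary column would collapse it to a single bin and erase its
information. RGB maps min-max scale each channel to 0-255 over occupied
voxels; a degenerate single-value channel maps to 255 (pinned). The
mid-sagittal mirroring plane is the z midline of the rendering grid,
matching the CCF convention.

# Spatially tuned clustering of full morphologies

Pairwise similarity is the product of the cosine similarity of z-scored
47-dim vectors and a spatial coefficient `exp(-d_ij / d_max)`, where
`d_max` is the population's maximum pairwise soma distance — max
normalization keeps the exponent in [-1, 0] so the spatial term lies in
(0, 1] and can only shrink similarity. Cosine similarity can be negative;
affinities for spectral clustering are clipped at zero (a shift would
distort the ratio structure of strong affinities). Spectral clustering is
the standard normalized-Laplacian embedding with row normalization,
followed by k-means under an explicit seed with 20 restarts. Disconnected
affinity graphs are clustered per component, with the cluster budget split
proportionally to component size. The silhouette implementation follows
the textbook `(b - a)/max(a, b)` with Euclidean distances and is
cross-checked in the tests against an independent implementation.

# Arbors

Axonal arbors are found by spectral clustering of all axonal nodes under
the affinity `exp(-d_uv / sigma)`. The affinity needs a length scale —
`exp(-d[um])` underflows at whole-neuron distances — and `sigma = 100 um`
is the default, matching the packing scale of dense terminal arbors;
axons above 2000 nodes are subsampled deterministically along arc length
and the remaining nodes assigned to the nearest labeled node. The
automatic count maximizes the *relative* eigengap
`(lambda[k+1] - lambda[k]) / (lambda[k+1] + delta)` with `delta = 1e-3`.
The regularizer is the load-bearing choice: for k well-separated clusters
the first k eigenvalues are essentially zero, so spurious gaps *between*
near-zero eigenvalues (which an absolute eigengap happily selects high in
the spectrum) are suppressed, while the true gap scores close to 1.
Regional counts are the mode over a region's neurons, ties resolved toward
the smaller count.

Arbor volume is a rotated bounding box. A pure PCA-aligned box is not
rotation-equivariant on degenerate point sets — the covariance of a cube's
corners is isotropic, so PCA axes land on arbitrary (coordinate) axes —
so the box orientation is refined by minimizing the bounding volume over
rotations (Nelder-Mead), initialized at the PCA axes plus a fixed set of
rotations *relative to them*. Because every start is defined relative to
equivariant axes, the estimate is invariant under rigid motion of the
input, and for a cube corner set it recovers edge cubed to machine
precision. Maximal density counts member nodes within 20 um (self
included; ties on the densest node go to the lowest id), and arbors are
proximal when the densest node lies within 750 um of the soma (boundary
inclusive, pinned) — A1..Ak labels ascend with that distance.

# Primary axonal tracts and projection motifs

The primary tract starts from the longest axonal soma-to-tip path and
iteratively deletes its terminal segment while that segment is shorter
than a reference length `L2`, re-terminating at the preceding bifurcation;
pruning stops when the terminal segment reaches `L2` or no internal
bifurcation remains. `L2` is the second-longest axonal *branch segment*.
The alternative reading — the longest other soma-to-tip path — was
rejected during development because a neuron whose distal arbor contains
two near-equal long paths would then have its tract pruned all the way
back to the first bifurcation, contradicting the purpose of the construct
(a long projecting trunk with distal twigs stripped).

Bundle radius profiles resample each tract to 200 equal-arc-length points;
at each index the bundle's points are projected onto their first two
principal axes and the radius is the 75th percentile (linear interpolation,
type 7) of in-plane distances to the centroid. Classification compares the
mean radius over the first and last 5% of arc length, floored at
`eps = 10 um`: divergent when the terminal/soma ratio is at least
`tau = 2`, convergent when the inverse ratio is, else parallel. The floor
makes identical-tract bundles (radius identically zero) parallel rather
than undefined; both `tau` and `eps` are exposed because the source
literature describes the motifs qualitatively, with spreads moving between
sub-millimetre and millimetre scales.

# Varicosity detection

The axon skeleton is partitioned into consecutive 20-um fragments and
sampled at one-voxel spacing. Intensity is the trilinear image value;
radius is the half-width at half-maximum of the intensity cross-section
perpendicular to the local tangent (mean over 8 rays, capped at 10 um).
Candidates are intensity-profile local maxima that coincide within +/-2
samples with a radius-profile maximum; both profiles are smoothed with a
5-sample running mean, and peaks require a prominence of 5% of the branch
profile range (any discrete peak finder needs a prominence floor; both are
parameters). Plateau maxima — common after 8-bit quantization — report
their centre sample. A candidate survives when its radius is at least 1.5
times the baseline (the median radius of its host fragment excluding +/-2
um around the peak — a robust, local reading of "surrounding axon") and
its 8-bit intensity exceeds 120; 16-bit inputs should be rescaled by their
0.999 quantile first. Survivors are de-duplicated greedily in descending
intensity order within 5 voxels. Detection counts are monotone
non-increasing in both thresholds.

TEB (terminaux) varicosities lie within 2 um arc length of an axonal tip —
roughly one varicosity diameter — all others are en passant (EPB). The six
radar features (count, TEB ratio, mean normalized distance to soma,
varicosities per varicosity-branch, fraction of branches bearing
varicosities, mean spacing between consecutive varicosities ordered by
distance to the soma) are a reconstruction: the source figure shows the
radar axes only graphically, so the set is pinned here and documented as a
convention, min-max scaled to 0-100 over the analyzed set.

# Cross-scale DS matrices

A neuron's cross-scale vector concatenates five z-scored blocks in fixed
order: microenvironment (18), full morphology (18), arbor (dendritic plus
two axonal arbors times four features, 12), tract motif (21), varicosity
(6) — 75 dimensions. The motif block is configuration, not ground truth:
tract length, terminus distance, node-radius delta, straightness, midpoint
and terminus coordinates, unit direction, and an 8-bin arc-length turning
angle histogram. The microenvironment block is transferred from the
same-region donor dendrite with the closest z-scored L-Measure vector.
Axons are arborized to exactly two arbors for comparability across
neurons.

A DS matrix entry `s_UV` is the mean Pearson correlation over all
cross-type neuron pairs; the diagonal `s_U` averages unordered within-type
pairs *excluding* self-pairs, which would otherwise bias every diagonal
toward 1. The diagonal therefore equals the mean of the within-type
correlation distribution summarized by `intra_moments()` (a consistency
the tests assert). Distances between per-scale DS matrices are
`1 - Pearson` over upper-triangle-with-diagonal vectorizations.
Similarity-vs-distance curves bin pairs by soma distance up to 4 mm
(about the scale of brain regions) and report per-bin means/SDs plus the
overall distance-similarity Pearson correlation.

# Neurite co-occurrence and regional modules

The brain-level foreground threshold is
`0.9 min(max(mu + 1.5 sigma, 400), 1000)` on 16-bit intensities. Blocks
are pre-filtered (compressed size below 1.7 MB or maximum below 300 skips
the block), denoised by local mean subtraction (5^3 window, negatives
clipped — the named denoising plugin's algorithm is undocumented, so the
simplest adaptive filter is pinned), and scored for anisotropy per
16x16x4-voxel cuboid (nearest-neighbor upsampled to 16^3 to undo the 4x z
anisotropy): `(S1-S2)/(S1+S2) * (S1-S3)/(S1+S3)` over the eigenvalues of
the intensity-weighted coordinate covariance, which is near 1 for
line-like content and near 0 for blobs and flats. The salience (denoised
intensity times anisotropy) is thresholded at `0.1 thresh`.

Density matrices normalize per-brain neurite voxel counts to column sums
of one. Correlation maps use weighted Spearman — average ranks, then
weighted Pearson — with per-brain weights equal to the reciprocal of each
transgenic line's brain count (mean weight for unlabeled brains); with
uniform weights the estimator reduces exactly to ordinary Spearman, which
is the only cross-check available since the reference estimator's
internals are unpublished. Target-correlated region sets collect regions
with correlation at least 0.5 (boundary inclusive).

Module detection clusters `1 - M_c` with average linkage and walks the
dendrogram top-down: a node is accepted as an initial module when it has
3-30 leaves *and* its merge height is at most `1 - c_min` with
`c_min = 0.4` — under average linkage the node height is exactly one minus
the mean correlation between its two sub-clusters, so the gate demands
that the halves of a module actually co-vary. Without the gate, two
genuine modules that happen to share a small subtree would be reported as
their union. Initial modules then lose regions occurring fewer than twice
across all target sets, and survive as tight modules with at least two
remaining regions, reported with their consistency (mean pairwise
correlation). On unstructured matrices the height gate alone already
rejects every candidate cluster.

# Pruning filters

All branch angles in the pruning suite are measured between the child
chord and the direction back toward the soma, so a straight continuation
scores 180 degrees and `< 80` is a sharp turn-back — the only reading
under which "less than 80 degrees" is excessive. The crossover filter
treats multifurcations and ancestor/descendant bifurcation pairs within 5
voxels as suspect sites, removes sub-80-degree children, and removes
80-100-degree children in pairs when they oppose each other by more than
150 degrees (a crossing fiber read as two spurs); the straightest
continuation is never removed. The secondary-soma filter scores each
segment of the soma-candidate path by its length-weighted deviation from
the radial direction *away* from each soma — a neurite grown from a soma
deviates little from its own radial direction — cuts at the first segment
whose deviation integral favors the candidate, and always removes the
candidate blob itself. The winding filter removes terminal branches whose
tips have path/Euclid ratio strictly above 3 (soma-coincident tips count
as infinite). `apply_all()` runs the four filters independently on the
input, keeps the node-level intersection, drops fragments disconnected
from the soma, and discards results below 20 nodes. The suite is
idempotent on its own output.

# Synthetic generators: what they emulate, and what they do not

Every generator is a pure function of `(spec, seed)` — the global RNG
state is saved and restored, and identical calls are bit-identical.

* `synth_neuron()` grows log-normal branch lengths, Gaussian bifurcation
  amplitudes, per-step angular jitter, and optionally an axon with a long
  tract and compact distal arbors; generated trees always pass
  `validate()`, and realized branch-length means track the spec within
  sampling error. Ground-truth arbor membership is recorded in the meta
  data for recovery tests.
* `synth_population()` plants within-region feature correlation with a
  shared region-level latent factor (variance rho, idiosyncratic variance
  1 - rho). Region factors are drawn mutually orthogonal and mean-centred:
  random factors would overlap by about `1/sqrt(n_features)` and leak a
  bias of order `rho/sqrt(n_features)` into cross-type mean correlations,
  confounding the diversity readout.
* `synth_tract_bundle()` draws soma and terminal points in discs whose
  radii encode the convergent / divergent / parallel geometry.
* `synth_image_block()` renders a tube of stated radius and axial
  intensity, adds isotropic Gaussian varicosity bumps to both radius and
  intensity, and applies Poisson shot noise and Gaussian read noise last
  (both optional, keeping a noise-free mode for exact tests).
* `synth_density_matrix()` plants correlated region blocks through
  per-brain latent factors under monotone positive marginals, then
  normalizes columns. The damped-exponential marginal keeps single regions
  from dominating column sums; note that column normalization necessarily
  couples regions by about `-1/n_regions`, which is visible as a small
  negative shift in null correlations.

What the generators do *not* emulate: real arbors are not isotropic blobs
and real tracts are not straight tubes; imaging artefacts (striping,
attenuation, registration error) are absent; varicosities are ideal
isotropic Gaussians; populations have no spatial feature gradients within
a region. Passing the recovery tests therefore demonstrates that the
algorithms are correct implementations with the stated statistical power
on clean planted structure — not that their defaults are optimal on any
particular imaging corpus.

# Problem sizes and determinism

The test-suite and acceptance-script sizes were chosen so every check runs
comfortably on a single core: 50 random trees for the feature oracle; 45
regions x 50 brains x 20 seeds for module recovery (three planted 5-region
modules at rho = 0.8); 20 blob neurons for arbor recovery; 100 bundles of
12 tracts for motif classification; 64x64x32-voxel blocks with three
planted bumps, noise-free and at shot-noise SNR 5 (20 seeds); populations
of 50 neurons per type at rho in {0, 0.5, 0.8}; 100 random trees for
pruning idempotence. Every stochastic step takes an explicit integer seed;
k-means restarts are pinned (10-20 depending on the op), and all
tie-breaks resolve toward the lowest node id or the smaller count.

# Known limitations

* The feature set follows the Vaa3D dialect; values differ from the
  L-Measure server where the conventions differ (untrimmed spans,
  fragmentation counting).
* Spectral arborization assumes roughly isotropic arbors; strongly
  elongated terminal fields can split across clusters at the default
  sigma.
* The varicosity radius estimate (HWHM against the half of the centre
  intensity) assumes a dark background; strong background haze biases the
  radius upward. The detector expects 8-bit-equivalent intensities.
* The image path operates on single blocks (up to about 512^3 voxels);
  whole-brain orchestration is a thin loop left to scripts.
* Module detection inherits the instability of hierarchical clustering
  near the size limits; the height gate makes the planted regime reliable
  but borderline modules (consistency near 0.4) can toggle between seeds.
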