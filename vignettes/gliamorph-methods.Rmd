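---
title: "Morphometric phenotyping of microglia with gliamorph: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric phenotyping of microglia with gliamorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliamorph)
```

## The scientific problem

Microglia — the resident immune cells of the retina and central nervous
system — signal their functional state through their shape. Homeostatic
cells are highly ramified, with many fine, high-order processes surveying a
large territory; reactive cells de-ramify toward a compact, amoeboid form.
In models of ocular hypertension this shift unfolds over weeks and can
partially reverse, so a quantitative, unsupervised readout of where a
*population* of cells sits on the homeostatic-to-reactive spectrum is more
informative than any single hand-picked measurement.

`gliamorph` implements that readout end to end, starting from single-cell
tree reconstructions (SWC files, one traced cell per file):

1. a fixed 14-feature morphometric panel per cell, with group statistics;
2. the topological morphology descriptor (TMD): a persistence barcode of
   each tree under a radial-distance filtration, vectorized as a persistence
   image;
3. bootstrap aggregation of cells into condition-labelled pseudo-samples,
   embedded by PCA and UMAP;
4. pseudotime along a principal graph, treating persistence-image pixels as
   genes, rooted at a control condition;
5. marker-image quantification (particle counting, two-channel
   colocalization) with the accompanying group statistics.

A seeded synthetic-data module generates all inputs, so every claim the
package makes can be verified by simulation with known ground truth.

## The synthetic cohort generator

The generator compresses the ramified-to-amoeboid continuum into one latent
scalar, the reactivity `phi` in [0, 1]. Every structural parameter is a
(homeostatic, reactive) pair interpolated linearly by `phi`:

| parameter | homeostatic (phi = 0) | reactive (phi = 1) | units |
|---|---|---|---|
| mean primary processes (Poisson) | 6 | 3 | count |
| mean segment length (Gamma, shape 4) | 14 | 7 | um |
| bifurcation probability per segment | 0.90 | 0.25 | — |
| maximum branch order | 6 | 2 | — |

Child directions follow the parent direction plus isotropic Gaussian noise
(sd 0.4 rad), constrained to point away from the soma: processes radiate
outward, which also guarantees that the radial-distance filtration is
monotone along every root-to-leaf path, so every persistence bar has
birth >= death. The soma radius of 6 um matches the 12 um maximum soma
diameter convention used when seeding filament tracing. Expected tip count,
total length, branch order and territory all decrease monotonically in
`phi` (verified as a property test over 50-cell means).

A cohort assigns each condition a Beta distribution over per-cell `phi`
(`phi_mean`, `phi_concentration`). The default concentration of 30 gives a
within-condition standard deviation of about 0.09 — substantial biological
heterogeneity without losing condition identity. The default presets mimic
an ocular-hypertension time course with a treated arm:

```{r presets}
default_conditions()
```

The peak-reactivity condition (0.85) should land farthest from the
normotensive root on the trajectory, and the partial-reversal condition
(0.40) between the early (0.35) and peak conditions. Default cohort size is
120 cells per condition; per-condition counts entering this kind of
analysis are rarely published, so this is a package choice, documented
here, not a reproduction of a reported number.

What the generator does *not* emulate: tracing artifacts (spurious short
filaments), anisotropic z-resolution, incomplete cells at image borders,
multi-point somas (the SWC reader collapses those when they occur in traced
data), or any correlation between soma size and reactivity. Passing tests
therefore demonstrate that the pipeline recovers a known latent axis under
clean, well-specified conditions — not that it is robust to every artifact
of real tracing.

The marker-image generator places non-overlapping disks ("cells") in a 2D
field; each disk's two channel intensities are drawn from a bivariate
normal (Gaussian copula with normal marginals, mean 0.55, sd 0.1), so the
target inter-channel correlation is exact in expectation. Gaussian
background noise is added and the rendered image clamped to [0, 1]; with
the default intensity scale, clamping is a > 4 sigma event and negligible.

## The 14-feature panel

Field practice names a handful of features (sphericity, circularity, node
counts, branch lengths, betweenness); a *fixed* panel is needed for the
fraction-of-features-changed readout to be well defined. The panel is:
node, branch-point and tip counts; total and mean branch length (a branch
is a maximal path between soma/branch-point/tip endpoints); maximum
centrifugal branch order; mean radial distance; cell volume and surface
area from radius-annotated conical frusta plus the soma sphere
(deterministic and mesh-free, matching the SWC data model, rather than
voxelization); soma volume; sphericity `pi^(1/3) (6V)^(2/3) / A`;
circularity `4 pi A / P^2` of the convex hull of the xy-projection;
ramification index (tips per primary); and mean normalized betweenness
centrality.

Two definitional choices deserve a note:

* **Circularity** is an imaging-plane quantity — the xy plane is the
  microscope's focal plane and is physically distinguished. It is therefore
  invariant under in-plane rigid motions but not under arbitrary 3D
  rotations; the other 13 features and the barcode are fully rigid-motion
  invariant, and the tests check exactly that split.
* **Volume/area** treat the soma as a sphere and each segment as a frustum;
  a soma-only cell has sphericity exactly 1. Collinear node subdivision
  leaves lengths, areas and volumes unchanged (midpoint radii make frustum
  sums exactly additive), which the tests verify.

With two conditions each feature is compared by a Welch t-test (the robust
default when only "t-test" is specified); with three or more, one-way ANOVA
with Tukey HSD post-hoc pairs. Zero-variance features are skipped and
flagged rather than tested.

## TMD barcodes and persistence images

The filtration function is the Euclidean distance from the soma (path
distance is available as an option). Descending from the tips: each leaf
opens a component at its radial distance; when components meet at a branch
point the elder rule keeps the component with the larger birth and closes
each other component as a bar `(birth, f(branch point))`; the surviving
component closes at the soma as the maximal bar `(max tip distance, 0)`.
Bar count equals tip count. Ties in birth are broken toward the smaller tip
id — relevant only for exactly symmetric synthetic trees. Note that every
primary process that loses its merge *at the soma* also dies at filtration
value 0, so a cell with k primaries has k death-zero bars; the maximal bar
is the one with the global maximum birth. The implementation is checked
bar-for-bar against an independent union-find simulation of the descending
filtration on random trees.

The persistence image places an isotropic Gaussian at each bar's
(birth, death) on an R x R grid and normalizes to unit mass. Three
quantities are not fixed by common usage and are config-exposed with these
defaults:

* **resolution** R = 100, i.e. the 10,000-pixel vector the downstream
  stages treat as an expression profile;
* **bounds** `(0, 1.05 * max tip distance over the cohort)` — cohort-global
  so that all cells share one grid, a prerequisite for pixel-wise averaging
  in bootstraps; a bar outside the bounds is an error, not a silent clip;
* **bandwidth** sigma = L_max / 20 — scale-relative smoothing keeps images
  comparable across cohorts of different spatial extent;
* bars are **unweighted** (persistence weighting available as an option).

## Bootstrap aggregation and embedding

Each pseudo-sample is the pixel-wise mean persistence image of 100 cells
drawn with replacement from one condition; 400 pseudo-samples are collected
per condition (both config). Averaging suppresses single-cell noise and
minor tracing artifacts, at the cost of shrinking within-condition spread
by a factor of ~10 — a property with consequences for the trajectory stage
(below). PCA is fitted on the pooled pseudo-samples of all conditions (a
shared basis is required for cross-condition geometry); the first 10 PCs
feed UMAP with `n_neighbors = 50`, `min_dist = 1.0`, `spread = 3.0`.

Determinism: UMAP runs seeded and single-threaded; exact-duplicate rows are
collapsed before embedding and mapped back, so identical pseudo-samples get
identical coordinates and a fixed seed reproduces every output byte for
byte. PCA uses an eigendecomposition of the n x n Gram matrix when pixels
outnumber samples — exact, and cross-checked against a dense SVD oracle.

Condition separation is reported as the mean pairwise silhouette over
condition labels in UMAP coordinates plus centroid distances — the
quantitative counterpart of populations "clustering separately".

**A caveat that matters for interpretation:** bootstrapping is only a
faithful view of a condition when the cell population is large relative to
the resample size. Two independent n-cell cohorts drawn from the *same*
distribution differ in their mean image by about `sd * sqrt(2/n)`, while
pseudo-samples spread around their cohort mean by about
`sd / sqrt(sample_size)`; their relative displacement is therefore
`sqrt(2 * sample_size / n)`. With the default 100-cell bootstrap, a 120-cell
cohort gives displacement 1.29 — identically distributed cohorts then
*visibly separate* in the embedding (measured null silhouettes of 0.2-0.6),
through no biological difference at all. At 600 cells per condition
(displacement 0.58) the null silhouette drops to ~0.05. UMAPs of
bootstrapped morphologies from small cohorts should be read with this in
mind, and the package's null-behaviour checks run in the bootstrap-valid
regime (population at least several times the resample size), which is also
the regime of whole-tissue microglia populations.

## Trajectory and pseudotime

Pseudo-samples are clustered by Leiden community detection (modularity
objective, resolution 1.0, k = 20 nearest neighbours — all config) and a
principal graph is built as the minimum spanning tree over cluster
centroids; each pseudo-sample projects to the nearest point on the nearest
edge and pseudotime is the geodesic arc length from the root node (the
centroid nearest the root condition's samples), shifted so the minimum over
samples is exactly zero. The MST surrogate keeps the contract of
reversed-graph-embedding tree learning — an acyclic, single-partition
backbone — while remaining transparent and directly testable (tree-metric
identities, re-rooting identities).

One design choice here was genuinely open and was settled by measurement:
**in which space to learn the backbone**. Building the MST on 2D UMAP
coordinates is appealing (it matches what the plots show) but unreliable
for exactly the data this pipeline produces: bootstrap averaging makes each
condition's cloud compact, the UMAP fuzzy graph then has no cross-condition
edges, and the mutual placement of the clouds in the 2D layout becomes
essentially arbitrary — across seeds, the recovered ordering of conditions
varied wildly. Distances in the retained PC space, by contrast, are
faithful: condition-mean distances there increase monotonically with the
ground-truth reactivity gap. The backbone (kNN graph, Leiden clusters,
centroids, MST, projections) therefore lives in PC space, and the UMAP is
the display layout carried alongside. With this choice the Spearman
correlation between a pseudo-sample's mean ground-truth reactivity and its
pseudotime is ~0.97 across seeds, and the time-course presets order
correctly (peak farthest, reversal intermediate).

Pseudotime validity is checked by `pseudotime_recovery()`: Spearman rho of
ground-truth mean phi vs pseudotime with a permutation p-value. With only
two conditions the rank correlation is trivially ±1 and the result is
flagged as under-determined.

## Marker quantification and statistics

`count_particles()` follows the classic recipe: Otsu auto-threshold (the
specific auto-threshold family used in common macros is unstated, so Otsu
is the default and the threshold is config-exposed), distance-transform
watershed to split touching objects, and connected components of at least
30 px (config; suppresses noise specks). Intensities are min-max normalized
before thresholding, making counts invariant to linear intensity rescaling.

`colocalize()` reports Pearson's r over in-mask pixels with the standard
t-test p-value and a Fisher z 95% interval, `tanh(atanh(r) ± 1.96/sqrt(n-3))`
— at |r| = 1 the interval degenerates to the point and p to 0. Mander's
coefficients are out of scope. `compare_groups()` dispatches Welch t
(2 groups) or one-way ANOVA + Tukey HSD (3+), reporting mean ± SEM; the
Tukey p-values are verified against an explicit studentized-range oracle
and the t-test's type-I error is calibration-tested under the null.

## Numerical and degenerate-input conventions

* Soma-only cell: all branch features 0, sphericity 1, barcode {(0, 0)}.
* Multi-point somas in traced SWC: extra type-1 nodes collapse onto the
  root (the radial filtration needs one soma point); the root keeps its
  coordinates.
* Unknown SWC struct_type codes are accepted as process nodes.
* Zero-variance features/channels: skipped and flagged, never silently 0.
* Rank-deficient PCA input: retains the available components with a
  warning.
* A single Leiden cluster: the principal graph is one node; pseudotime
  degenerates to distance-to-centroid with a warning.
* A minimum-branch-length artifact prune (`prune_short_branches()`) is
  provided for spurious tracing filaments but deliberately **not** applied
  by default: no principled threshold is available, and the bootstrap + PCA
  averaging already damps small spurious filaments.

## Problem sizes

The test suite exercises the full published defaults (120 cells x 5
conditions, 100-cell bootstraps, 400 pseudo-samples per condition, 10,000
pixels) in its end-to-end acceptance blocks, and scaled-down cohorts
(25-60 cells, 40-100 pseudo-samples) in module-level property tests; these
sizes are the package's own choices for a thorough-but-quick default test
run. `scripts/acceptance.R` re-runs the full-size analysis from scratch.

## Known limitations

* The principal graph is an MST over cluster centroids, not an iterated
  reversed-graph-embedding fit; branchy topologies with loops or very
  unequal cluster densities may be summarized coarsely. The full iterative
  fit is future work behind the same interface.
* Persistence images use a single global bandwidth; cohorts mixing very
  small and very large cells blur the small ones relatively more.
* The synthetic generator's single latent axis cannot represent phenotypes
  that differ in *kind* rather than degree (e.g. rod-like microglia).
* 2D marker images only; 3D stack quantification is out of scope.
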