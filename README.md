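# gliamorph

Unsupervised morphometric phenotyping of microglia from single-cell tree
reconstructions, for researchers studying neuroinflammation and
neurodegeneration (retina, optic nerve, CNS) who quantify the
ramified-to-amoeboid reactivity spectrum of microglia populations.

Microglia signal their functional state through shape: homeostatic cells are
highly ramified, reactive cells de-ramify toward amoeboid forms, and disease
time courses move whole populations along this spectrum — sometimes partway
back. `gliamorph` turns a folder of traced cells (SWC files) into that
population-level readout, and ships a seeded synthetic-data generator so the
entire analysis is testable end to end with known ground truth.

## What it computes

**Topological morphology descriptor (TMD).** Each cell is a rooted tree; the
filtration f(v) = ‖v − soma‖ descends from the process tips toward the soma.
Each tip opens a component at its radial distance; at a branch point the
elder rule keeps the component with the larger birth and closes the others
as bars (birth, f(branch point)); the survivor closes at the soma as
(max tip distance, 0). The barcode has one bar per tip. It is vectorized as
a persistence image: a sum of isotropic Gaussians at the (birth, death)
points on a shared 100 × 100 grid, normalized to unit mass — a 10,000-pixel
vector per cell.

**Bootstrap phenotyping.** Condition pseudo-samples are pixel-wise means of
100 cells resampled with replacement, 400 pseudo-samples per condition. PCA
(10 components) followed by UMAP (n_neighbors = 50, min_dist = 1.0,
spread = 3.0) visualizes population structure; condition separation is
quantified by pairwise silhouettes and centroid distances.

**Pseudotime.** Treating pixels as genes, pseudo-samples are clustered by
Leiden community detection on a kNN graph of the PC scores; the principal
graph is the minimum spanning tree over cluster centroids, each sample
projects onto its nearest edge, and pseudotime is the geodesic arc length
from the root node (nearest the control condition), with the minimum shifted
to zero. A UMAP with the manhattan metric provides the display layout.

**Feature panel and statistics.** A fixed 14-feature panel per cell
(counts, lengths, branch order, frustum-based surface/volume, sphericity,
circularity, ramification index, betweenness centrality), compared across
groups by Welch t-test or one-way ANOVA + Tukey HSD. Marker images are
quantified by Otsu threshold + watershed particle counting, and two-channel
colocalization is reported as Pearson's r with a t-test p-value and Fisher z
95% interval.

## Worked example

A synthetic five-condition cohort mimicking an ocular-hypertension time
course with a treated arm (reactivity means: normotensive 0.10, 2 wk 0.35,
4 wk 0.85, 6 wk 0.40, treated 0.25), kept small here so it runs in seconds:

```r
library(gliamorph)

gen <- generate_cohort_cells(cohort_spec(default_conditions(n_cells = 40), seed = 1))
cpi <- cohort_persistence_images(gen$cells)               # barcodes + images
bs  <- bootstrap_images(cpi$pixels, gen$info$condition,
                        bootstrap_config(sample_size = 40, n_bootstraps = 100, seed = 1))
tr  <- fit_trajectory(bs, trajectory_config(root_condition = "normotensive", seed = 1))
pseudotime_by_condition(tr)
#>      condition median_pseudotime mean_pseudotime   n
#> 1 normotensive      3.972685e-06    0.0005871578 100
#> 2     OHT_LXB4      1.288173e-02    0.0132675650 100
#> 3      OHT_2wk      1.949320e-02    0.0196732469 100
#> 4      OHT_6wk      2.556832e-02    0.0260724296 100
#> 5      OHT_4wk      6.931823e-02    0.0680750682 100
```

The medians order the conditions along the reactivity axis: the control sits
at the root, the treated arm just beyond it, and the 4-week peak-reactivity
population lies farthest; the 6-week population falls between 2 and 4 weeks,
the partial-reversal signature. Marker quantification on a synthetic
two-channel image:

```r
img <- generate_marker_image(image_gen_params(seed = 1))
q   <- count_particles(img$channels$ch1, intensity_channels = list(ch2 = img$channels$ch2))
q$particle_count
#> [1] 12
ce <- correlate_expression(q$particles$mean_intensity, q$particles$mean_ch2)
#> marker correlation: r = 0.79, p = 0.00217, 95% CI [0.40, 0.94]
```

The whole pipeline also runs from one config via `run_pipeline()` or the
`exec/gliamorph` command line
(`gliamorph all --outdir out/ [--config cfg.yaml] [--seed N]`), writing
per-stage TSVs and a JSON run manifest with seeds and checksums. See the
methods vignette (`vignettes/gliamorph-methods.Rmd`) for the model,
parameter meanings and design choices.

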