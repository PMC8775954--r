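---
title: "Methods: microglia morphometry and shape-mode analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microglia morphometry and shape-mode analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and numerical choices behind
`micromorph`, in the spirit of a methods section: what is computed, under
which assumptions, and where a design decision was genuinely open.

## The measurement problem

Microglial activation state is reflected in cell shape. Inflammatory cells
are swollen and near-circular (amoeboid); surveillant or restorative cells
extend thin branched processes (ramified), with transitional, elongated and
rod-like forms in between. Given Iba-1-stained fluorescence fields from an
experiment crossing treatment arms (healthy control, injury, treated injury)
with exposure times, the pipeline quantifies each segmented cell by four
geometric features and, at the population level, by membership in a small
number of recurring shape archetypes ("shape modes"). Differences across
arms and times are then tested nonparametrically.

## Segmentation

**Thresholding.** Fluorescence foreground is bright, and binarization is
`intensity >= t`. Seven classical threshold selectors are implemented from
their literature definitions (isodata: Ridler–Calvard; li: Li–Lee minimum
cross entropy via the Li–Tam fixed-point iteration; mean; minimum:
Prewitt–Mendelsohn with repeated 3-bin histogram smoothing; otsu; triangle:
Zack–Rogers–Latt; yen). Histogram methods use 256 bins over the observed
intensity range, so on 8-bit images candidates align with gray levels; the
test suite checks each selector against an exhaustive search of its defining
criterion. The Li iteration starts at the mean intensity and stops when
successive iterates differ by less than 1/512 of the intensity range (half a
gray level on 8-bit data); images whose histogram has an empty valley make
the cross-entropy criterion flat over the gap, in which case any threshold in
the flat region yields the same optimal partition. Li is the default working
method. The `minimum` method's smoothing is capped at 10,000 repetitions and
fails loudly if the histogram never becomes bimodal.

**Small-object removal.** Objects *strictly* smaller than
`min_object_area_px` are removed, so an object of exactly the cutoff area
survives. The default cutoff is 71 px², the operational constant for 40x
confocal fields of cortex; the physical rule behind such cutoffs —
`area_fraction x avg_cell_area_um2 / pixel_size_um²`, with a default half of
the 1600 um² average microglial area — is exposed as
`min_area_from_physical()`. The two are deliberately decoupled: at
3.4527 um/px the derivation gives 67.11 px², not 71, and the package does not
silently reconcile an applied constant with its nominal derivation. Users
with calibrated pixel sizes should pass the derived value explicitly.

**Labeling.** Components are labeled with 8-connectivity by default so that
thin diagonal processes remain attached to their soma (4-connectivity is
available). Interior holes are filled after size filtering. Labels are
contiguous from 1.

## Per-cell geometry

**Perimeter.** Pixelation makes naive boundary-length estimators biased: the
raw 0.5-level (marching-squares) contour of a rasterized disk of radius 50 px
overestimates the continuum circumference by ~6.6%, and chain-code weightings
carry similar errors. The package therefore measures the length of a
*regularized* subpixel boundary: the 0.5-level contour is resampled to ~1 px
arc-length spacing, smoothed with a periodic Gaussian (sigma = 2 points), and
rescaled about its centroid to restore the raw polygon's enclosed area. This
brings the r = 50 disk within ~1% of 2πr and a 100 px square within ~1.5% of
its true perimeter, which is what the accuracy tests assert. Circularity
`4πA/P²` uses the pixel-count area, so slightly exceeding 1 is possible for
small round objects and values are reported unclamped. A single pixel yields
the regularized length of its half-pixel diamond (~2.7 px), documented as the
degenerate-case convention.

**Axes.** Major/minor axis lengths are those of the ellipse with identical
normalized second central moments (4·sqrt of the coordinate covariance
eigenvalues, pixel centers as unit masses); aspect ratio is always
major/minor ≥ 1. Objects with fewer than 3 pixels or collinear pixels are
flagged degenerate, excluded from shape fitting, and counted in the QC log.

**Quadrants and edges.** Each mask is split into four equal tiles (sizes
differ by at most 1 px for odd dimensions) *after* segmentation, and any cell
touching a tile edge is discarded — including cells cut by the quadrant
boundary itself, which are removed from both adjacent tiles. Tile edges
rather than only outer image edges are used because a cell truncated by the
quadrant cut suffers exactly the same straight-edge artifact as one truncated
by the field of view; the alternative (outer edges only) would measure
half-cells.

## Shape modes

Outlines are extracted at the 0.5 level of each (hole-filled) object and
regularized as above; contours are resampled to `n_points = 50` equally
spaced boundary points — enough to resolve thin processes at the package's
default synthetic scale — by iterating the arc-length resampling to a fixed
point so that consecutive spacing is uniform and the operation is idempotent.

**Registration** removes similarity transforms: centroid to origin, unit RMS
radius, rotation of the principal axis of the point set onto the horizontal.
The 180° ambiguity of the principal axis is resolved by requiring a
nonnegative third moment of the x coordinates (falling back to y for
x-symmetric shapes); orientation is made counterclockwise, and the point
sequence starts at the largest-x boundary point (first index on ties).
Mirror images are *not* identified: reflection is a biologically meaningful
difference for chiral branch arrangements, and identifying mirrors would
silently halve the shape space. Users can mirror contours upstream if they
want reflection invariance.

**Embedding and clustering.** Principal components are fitted on the
registered training vectors; the number of retained components defaults to
the smallest number explaining ≥ 90% of variance, capped at 20 — enough for
faithful reconstruction while keeping k-means in a low-dimensional, stable
regime. k-means uses k-means++ seeding with 10 restarts and Lloyd iterations
at a fixed seed; on small inputs the converged inertia is checked against the
exhaustive-partition optimum in the tests. The split is 80:20 train:test at
the cell level, stratified by image so no condition is absent from training.
k = 5 is the default mode count, balancing interpretability against the
spectrum of microglial forms; all cells (train and test) are assigned to
their nearest centroid in score space, ties broken toward the lower mode
index.

Because raw cluster indices are arbitrary, modes are renumbered 1..k by
decreasing median member-cell area, making labels comparable across runs and
seeds. One *global* model is fitted over all arms and times — frequency
tables comparing conditions are only meaningful when every condition is
scored against the same basis. A Ward dendrogram over the k centroids orders
modes in heatmaps and overlays.

## Population statistics

Feature distributions are summarized per (group, exposure time) with the
individual cell as the statistical unit, pooled across images within a
condition; per-image aggregation is available for users concerned about
pseudoreplication. Fold changes are ratios of medians against the healthy
control at the same exposure time (medians, not means, for consistency with
median/IQR reporting of skewed morphology distributions; the mean is
configurable). Group comparisons use the tie-corrected Kruskal–Wallis test
(chi-square approximation, df = groups − 1) followed by Dunn's pairwise
z statistics on the pooled ranks with tie correction. The family-wise
adjustment defaults to Bonferroni — the conservative, assumption-free choice
when the post hoc method is otherwise unspecified — with Holm and none as
options; α = 0.05.

qPCR fold changes follow ΔΔCq: Cq values may first be centered by the
all-sample median (a uniform shift that cancels in ΔΔCq and is therefore a
toggle, kept because centered intermediate ΔCq values are easier to
inspect), then ΔCq against the housekeeping gene, ΔΔCq against the control
group's median ΔCq, and fold change `2^(−ΔΔCq)`. The per-group summary is
`2^(−median ΔΔCq)`, which makes the control group's own fold change exactly 1
for any group size; bootstrap 95% CIs (10,000 seeded resamples) are optional.

## The synthetic generator

The generator emulates what the downstream stages need from an Iba-1 field:
bright cell bodies with 0–6 processes on a dark background, drawn from five
parameterized shape classes (amoeboid, transitional, ramified, elongated,
rod) whose mixture varies by condition and time. Rendering is binary
silhouette → 1 px Gaussian blur (anti-aliased edge) → linear mapping to
`[bg, fg]` → additive Gaussian noise → optional Poisson shot noise →
clipping. Cells are placed by rejection sampling with 100 retries under a
minimum-separation constraint, guaranteeing a bijection between planted
cells and ground-truth labels.

Default class geometry (at the default 1 um/px) makes amoeboid cells the
largest and roundest, ramified the least circular, and rod the most
elongated; processes are anchored to the soma axis at evenly spread angles
with mild jitter, share one length/width draw per cell, and shorten by
1/elongation perpendicular to the axis. These three choices are deliberate:
independently drawn arm geometry or large angular jitter creates
mirror-image and axis-flip variants of the *same* nominal class, which are
genuinely distinct shapes under a registration that does not identify
mirrors, and they would split classes into multiple modes. The acquisition
pixel size is a free parameter (default 1 um/px) rather than a hard-coded
microscope constant.

The default condition series places amoeboid-heavy mixtures in the injured
arms early and shifts the treated arm toward ramified/branched classes
between 24 h and 48 h, so the end-to-end test can assert the expected
directional signature (decreasing median area and circularity, increasing
aspect ratio, frequency mass moving out of the amoeboid-like mode).

What the generator does **not** emulate: 3D/z-stacks, multi-channel
co-stains, touching or overlapping cells, point-spread functions,
photobleaching, uneven illumination, or background autofluorescence
texture. Passing tests therefore demonstrate the correctness of the
computational pipeline on images whose difficulty is controlled, not
robustness to every acquisition artifact of real confocal data; on real
images, threshold choice and the small-object cutoff remain the user's
responsibility.

## Reproducibility envelope

All randomness flows from explicit seeds; functions restore the caller's RNG
state. The pipeline fans a single global seed out to per-stage child seeds by
stable hashing of the stage name, so any suffix of stages rerun from the
previous stage's on-disk outputs reproduces the composed run bit-for-bit
(content hashes in `manifest.json` verify this). Serialized shape-mode
models (JSON, full precision) reload to identical assignments.

Problem sizes in the test and acceptance runs — 10 seeded bimodal images for
the threshold oracles, 500 + 500 cells for two-class recovery, 1000 cells for
five-class recovery, 10,000 null simulations for the type-I error of the
Kruskal–Wallis wrapper, and a 512×512, 8-image condition series for the
end-to-end signature — were chosen so each check is statistically meaningful
while the full suite stays comfortably runnable on a laptop.

## Known limitations

- Touching cells are not split (no watershed); the study design this
  pipeline mirrors counts merged cells as one object.
- Circularity depends on the perimeter estimator; values are comparable
  within this package but not across toolkits with different estimators (the
  estimator is recorded in the methods above for that reason).
- Near-circular cells make the registration rotation ill-defined; this is
  harmless for disks (rotation-invariant) but adds variance for
  almost-isotropic branched shapes.
- The chi-square approximation of the Kruskal–Wallis p value is asymptotic;
  at very small group sizes an exact/permutation test (as used in the test
  suite's cross-check) is preferable.
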