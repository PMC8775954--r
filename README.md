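# micromorph

Quantitative morphometry of microglia in 2D fluorescence micrographs.

Microglia change shape with their activation state: swollen, near-circular
*amoeboid* cells mark an inflammatory response, while *ramified* cells with
thin branched processes mark surveillant or restorative states. In brain-slice
injury models (e.g. oxygen–glucose deprivation with a candidate treatment),
the distribution of these morphologies across experimental arms and exposure
times is the readout of interest. `micromorph` implements the full analysis
path from an Iba-1-stained image to population statistics, for researchers who
need a reproducible, testable version of that readout.

## What it computes

1. **Segmentation.** A survey of seven automatic intensity thresholds
   (isodata, li, mean, minimum, otsu, triangle, yen; foreground = bright,
   `intensity >= threshold`), with minimum-cross-entropy (Li) thresholding as
   the working default, followed by removal of objects smaller than a cutoff
   (default 71 px²; the physical derivation `fraction x avg cell area /
   pixel_size²` is exposed as `min_area_from_physical()`) and hole filling.
2. **Per-cell geometry.** Area, perimeter (regularized subpixel boundary
   length), circularity `4πA/P²`, and the aspect ratio `major/minor` of the
   moment-equivalent ellipse. Images are split into four equal quadrants and
   cells touching any tile edge are discarded.
3. **Shape modes.** Cell outlines are resampled to 50 equally spaced boundary
   points, registered (translation, scale, rotation and start point
   normalized), embedded with principal components, and clustered with
   k-means (k = 5 by default) on an 80:20 train:test split. The fitted
   `shape_mode_model` is a classed object with `print`, `summary`, `predict`
   and `plot` methods, a Ward dendrogram over the mode centroids, and JSON
   serialization.
4. **Population statistics.** Shape-mode frequency tables (percent per
   condition), median fold change of each feature against the healthy control
   at the same exposure time, and Kruskal–Wallis tests with Dunn's post hoc
   pairwise comparisons (Bonferroni-adjusted by default, α = 0.05).
5. **Assay helpers.** PI cytotoxicity percent, EV purity
   (NTA particles / BCA protein), dot-blot signal-density ratios, and
   median-normalized ΔΔCq qPCR fold changes with bootstrap confidence
   intervals.
6. **Synthetic ground truth.** A generator of Iba-1-like fields — mixtures of
   amoeboid/transitional/ramified/elongated/rod cells with per-cell label
   masks — so every stage is validated against known truth; no acquisition
   data is required to test the pipeline.

## Worked example

```r
library(micromorph)

spec <- synthetic_spec(image_shape = c(512L, 512L), n_cells = 20L,
                       class_mixture = c(amoeboid = 0.5, transitional = 0.2,
                                         ramified = 0.2, elongated = 0.05,
                                         rod = 0.05),
                       noise_sd = 0.02, seed = 42)
gen <- generate_image(spec)
gen$image
#> fluor_image synthetic_seed42: 512 x 512 px, 1 um/px, intensity [0.0138, 0.862]

mask <- segment_image(gen$image, segmentation_config())
mask
#> labeled_mask: 512 x 512 px, 20 objects (8-connected)

cells <- extract_cells_quadrants(mask, pixel_size_um = 1, image_id = "demo")
head(cells[, c("label", "quadrant", "area_px", "perimeter_px",
               "circularity", "aspect_ratio")], 4)
#>   label quadrant area_px perimeter_px circularity aspect_ratio
#> 1     1        1     206       65.830       0.597        3.661
#> 2     3        1     545      111.299       0.553        1.752
#> 3     5        1     540       83.084       0.983        1.234
#> 4    10        2     451      153.291       0.241        1.331
```

The 20 planted cells are all recovered; 16 survive quadrant-edge removal.
Row 1 is a rod cell (aspect ratio 3.66), row 3 an amoeboid cell (circularity
0.98), row 4 a ramified cell (circularity 0.24). Fitting shape modes and
comparing groups:

```r
contours <- lapply(seq_len(nrow(cells)), function(i) {
  tile <- split_quadrants(mask)[[cells$quadrant[i]]]
  extract_contour(cell_masks(tile, cells$label[i])[[1]])
})
fit <- shape_mode_model(contours, k = 3, seed = 1, cell_area = cells$area_px)
fit
#> Shape-mode model: k = 3 modes, 50 boundary points, 2 PCs (91.0% variance)
#> Cells per mode: SM1:6  SM2:2  SM3:8

kruskal_wallis(list(healthy = rnorm(20, 0.8, 0.1), OGD = rnorm(20, 0.6, 0.1),
                    BEV = rnorm(20, 0.75, 0.1)))
#> Kruskal-Wallis: H = 34.11, df = 2, p = 3.913e-08
```

Modes are numbered by decreasing median member area; here SM1 collects the
large round cells and SM3 the branched ones. An end-to-end run — synthetic
condition series (or a directory of TIFFs with a design CSV), segmentation,
features, shape modes, statistics, heatmaps, and a content-hashed manifest —
is one call:

```r
cfg <- validate_config(system.file("extdata", "demo_config.yaml",
                                   package = "micromorph"))
run_pipeline(cfg)
```

or, from a shell, `Rscript inst/scripts/micromorph.R run --config <yaml>`.

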