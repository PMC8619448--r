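# orchardcrowns

Per-tree canopy monitoring in **semi-overlapping orchards** from
high-resolution multispectral rasters. When crowns of neighboring trees
merge within a row, no segmentation can outline a single crown — but the
planting pattern still says exactly where every tree stands. This package
masks canopy vs. soil by unsupervised clustering, reconstructs the full
planting grid from three anchor trunks, samples each tree's canopy through
an overlapping box of the maximum crown diameter, and classifies every tree
as missing/weak, normal, or big. It is aimed at precision-agriculture
practitioners working with ~0.5 m/pixel imagery of row-planted tree crops
(citrus and similar), and at anyone needing a fully synthetic, ground-truthed
test bed for such pipelines.

## Method at a glance

- **Canopy mask** — k-means (k-means++ seeding, 10 restarts) over raw band
  vectors; the vegetation cluster is the one with the highest mean NDVI
  = (NIR − red)/(NIR + red). An Otsu single-channel threshold is included as
  the classical baseline.
- **Tree localization** — centers p(i, j) = a₁ + i·u + j·v from three anchor
  trunks; directions from the anchors, magnitudes from the surveyed
  distances (e.g. 2 m in-row → 4 px, 6 m between rows → 12 px at 0.5 m GSD).
- **Crown boxes** — square windows of the maximum crown diameter (3 m →
  6 px) on every center; in-row neighbors overlap by 1 m and shared pixels
  count toward both trees.
- **Size classes** — per-parcel thresholds t₁ = min + avg/5 and
  t₂ = max − avg/5 on the per-box canopy pixel counts:
  class 1 (missing/weak) in [min, t₁), class 2 (normal) in [t₁, t₂),
  class 3 (big) in [t₂, max].
- **Outputs** — classified map raster (red/blue/yellow = missing/normal/big),
  per-tree CSV, per-row summaries; precision and
  F₁ = TP/(TP + (FP+FN)/2) against labeled masks.

## Worked example

Generate a study-sized synthetic orchard (10 rows × 25 trees, 2 m/6 m
spacing, 3 m max crowns, 10% missing trees), then run the full pipeline on
its image:

```r
library(orchardcrowns)

truth <- generate_orchard(orchard_scenario(seed = 7))
dir <- file.path(tempdir(), "demo")
write_fixture(truth, dir)

g <- truth$grid$positions
anchor <- function(ri, ti)
  as.numeric(g[g$row_index == ri & g$tree_index == ti,
               c("px_row", "px_col")])

cfg <- pipeline_config(
  input = file.path(dir, "image.tif"),
  anchors = list(r1t1 = anchor(0, 0), r1t2 = anchor(0, 1),
                 r2t1 = anchor(1, 0)),
  nodata = NA,            # keep the clipped background as a pixel population
  k = 3, seed = 7,
  out_dir = file.path(dir, "out"),
  expected_count = 250,
  truth_mask = file.path(dir, "truth_mask.tif"))

res <- run_pipeline(cfg)
print(res$thresholds)
print(res$summary$parcel)
print(res$score)
```

which prints:

```
class_thresholds: min 1, avg 21.504, max 30; t1 = 5.3008, t2 = 25.6992
  n_missing_weak n_normal n_big n_trees canopy_pixels
1              5      167    78     250          5376
mask_score: tp 3748, fp 0, fn 0; precision 1, recall 1, f1 1
```

All 250 planted positions are recovered; on this noise-free scene the canopy
mask matches the truth exactly (precision = F₁ = 1). The class thresholds
are relative to the parcel: counts below t₁ ≈ 5.3 pixels are missing/weak,
above t₂ ≈ 25.7 big. Note only 5 of the ~25 planted missing trees fall below
t₁ — a missing tree's box inherits canopy from its large neighbors through
the 1 m box overlap, the weak-vs-missing confound inherent to sampling
overlapping canopy with boxes.

Per-tree results are in `res$tree_table` (and `out/trees.csv`):

```
  tree_id row_index tree_index px_row px_col canopy_pixels canopy_m2 class
1       1         0          0      7      7            25      6.25     2
2       2         0          1      7     11            22      5.50     2
3       3         0          2      7     15            24      6.00     2
4       4         0          3      7     19            11      2.75     2
```

A command-line front end over the same functions lives at
`inst/cli/orchard.R`
(`orchard.R run|segment|localize|classify|score|synth --config cfg.yaml`).

## Package layout

- `R/raster_io.R` — parcel rasters, geotransforms, metric/pixel conversion
- `R/segmentation.R` — k-means canopy masking + Otsu baseline
- `R/localization.R` — planting-grid tree localization
- `R/crown_classify.R` — crown boxes, counts, thresholds, classes
- `R/mapping_report.R` — classified map and summaries
- `R/validation.R` — precision/F₁ scoring
- `R/synthetic_orchard.R` — ground-truthed scene generator
- `R/pipeline.R` — configuration and the end-to-end run
- `vignettes/orchard-crown-classification.Rmd` — methods and design notes
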