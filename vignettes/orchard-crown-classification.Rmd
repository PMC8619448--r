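---
title: "Delineating and size-classifying tree crowns in semi-overlapping orchards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating and size-classifying tree crowns in semi-overlapping orchards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orchardcrowns)
```

## The problem

In a semi-overlapping orchard the crowns of neighboring trees within a row
merge: rows are clearly visible from above, but the outline of any single
crown is not. Object-segmentation approaches that delineate individual crowns
therefore fail, yet per-tree information — is this tree missing, weak, normal
or unusually large? — is exactly what growers need for irrigation, pruning
and yield planning. `orchardcrowns` implements a five-stage pipeline that
sidesteps crown delineation entirely:

1. **canopy masking** — classify every pixel as canopy or soil from its
   spectrum, without labels;
2. **tree localization** — reconstruct every planted position from the
   surveyed planting pattern and three hand-picked anchor trunks;
3. **crown sampling boxes** — attribute canopy to trees through overlapping
   square windows centered on the planted positions;
4. **size classification** — split trees into missing/weak, normal and big
   by per-parcel thresholds on the canopy pixel counts;
5. **mapping and reporting** — render the classified map and per-row tables.

The package also ships a synthetic-orchard generator with complete ground
truth, so every stage (and the pipeline as a whole) is testable without
satellite imagery.

## Canopy masking

Pixel spectra of an already-clipped parcel raster fall into two or three
populations: tree canopy, bare soil, and — when the outside-parcel area is
clipped to a constant instead of being masked — the background. k-means over
the raw band vectors (Euclidean distance) separates these populations
without training data. `segment_kmeans()` uses k-means++ seeding with a
fixed seed and Lloyd iterations, and keeps the best of `nstart = 10`
restarts by within-cluster sum of squares. The restarts matter: with one
diffuse dominant stratum and two tight ones, a single greedy run can fall
into the local optimum that splits the dominant stratum and merges the other
two. Features are not standardized by default because all bands share one
radiometric scale; a `standardize` switch exists for mixed-scale stacks.

Cluster semantics are assigned spectrally, not visually:
`identify_vegetation_cluster()` picks the cluster with the highest mean NDVI
$(\mathrm{NIR}-\mathrm{red})/(\mathrm{NIR}+\mathrm{red}+\varepsilon)$, or the
highest green-band mean for RGB-only stacks, with ties broken toward the
lower cluster id. Background handling depends on how the raster carries it:
a nodata tag excludes those pixels from clustering outright, while untagged
(black) background is clustered as a real population — as it is in practice
when parcels are clipped — and `infer_background_cluster()` recognizes it as
the darkest cluster touching the raster border. On a noise-free scene with a
nodata tag only two distinct spectra remain, so `k = 3` then fails its
precondition by design (`k` exceeds the number of distinct vectors); the
natural configurations are `k = 3` with untagged background or `k = 2` with
a nodata mask.

A classical baseline, `segment_threshold()`, applies Otsu's
between-class-variance threshold to a single grayscale (NDVI when NIR is
available, otherwise the band mean). It uses one channel where k-means uses
all bands, and the test suite shows it scoring strictly below k-means once
soil reflectance becomes noisy — the motivation for clustering in the first
place. The in-package Otsu search is exact on few-valued histograms
(candidate thresholds at midpoints of consecutive unique values) and falls
back to a 256-bin histogram above 2048 unique values.

## Tree localization

Planting follows a surveyed pattern: in the study layout, trunks 2 m apart
within rows and rows 6 m apart, at a ground sampling distance of 0.5
m/pixel, i.e. steps of 4 and 12 pixels (`meters_to_pixels()`, round half
up). Three anchor trunks — the first two of row 1 and the first of row 2 —
fix the grid's origin and orientation. Directions are taken from the anchor
geometry but magnitudes from the declared distances, because anchors are
hand-clicked (half-pixel error each) while the distances are surveyed.
Candidate centers $p(i,j) = a_1 + i\,u + j\,v$ are generated for integer
lattice indices extended in both directions, rounded half-up per axis, and
kept only on in-bounds, non-nodata pixels; indices are renumbered from the
minimal kept lattice coordinates. Iterating lattice indices over a bounding
box (rather than scanning all pixels) gives the same kept set far more
cheaply.

Two accuracy regimes follow from the anchor error. With sub-pixel anchors
the recovered lattice is exact at any row angle. With pixel-rounded anchors
the *direction* of the 4-pixel in-row step can be off by several degrees,
and that error accumulates linearly along the lattice — on axis-aligned
grids it vanishes (rounded and exact anchors coincide), which is why
axis-aligned recovery is exact while rotated-grid tests use sub-pixel
anchors and assert a one-pixel tolerance. For field use the practical advice
is the same: pick anchors as far apart as the pattern allows, or refine them
to sub-pixel positions.

A localized grid confined by a nodata mask reproduces the planted count
exactly when the parcel boundary hugs the planted block. If the parcel
contains unplanted lattice positions (a wide soil margin, or the soil
corners of a rotated block inside a rectangular clip), those positions are
reported as additional near-zero-canopy trees — indistinguishable from
missing trees by geometry alone, which is the correct behavior for a purely
geometric stage.

## Crown sampling boxes and size classes

Each tree's canopy is sampled through a square box of side equal to the
maximum crown diameter (3 m → 6 pixels), anchored at
`center − floor(side/2)` and clipped at image edges; the even side biases
the window by at most half a pixel. With 2 m spacing, in-row neighbors'
boxes overlap by 1 m (2 pixels), and pixels in the shared strip count toward
*both* trees — attribution, not partition.

Per-parcel statistics of the box counts — `min_value`, `avg_value`
(arithmetic mean), `max_value` — define the two class boundaries

$$t_1 = \min + \mathrm{avg}/5, \qquad t_2 = \max - \mathrm{avg}/5,$$

and the classes: missing/weak for counts in $[\min, t_1)$, normal in
$[t_1, t_2)$, big in $[t_2, \max]$. The boundaries are always derived from
the three statistics (`threshold_bounds()`), never stored, and thresholds
are computed per parcel, never pooled. When $\max - \min < 2\,\mathrm{avg}/5$
the two boundaries cross ($t_1 > t_2$) and the intervals overlap; the rules
are therefore evaluated in order 1, 2, 3 with the first match winning, which
restores a total, monotone assignment (a warning reports the degeneracy).
The average includes every box, missing trees included — the formulas refer
to the canopies "in the parcel" without exclusions. Canopy size is carried
in pixels, with m² as a derived convenience column
(`pixels × resolution²`).

Two behaviors of this scheme are worth knowing. First, classification is
*relative to the parcel*: the same count can be "big" in a weak parcel and
"normal" in a vigorous one. Second, a missing tree flanked by large
neighbors inherits canopy through the box overlap, so its count can clear
$t_1$ — weak and missing trees genuinely confound with their neighbors'
vigor, and no disambiguation is attempted.

## Map rendering and reports

`render_class_map()` paints each box's class over a zero background. A pixel
covered by several boxes takes the class of the box with the nearest center
(squared pixel distance, ties to the lower tree id), making the map
independent of box iteration order. The legend follows the field convention:
red = missing/weak, blue = normal, yellow = big, black background; the RGB
values are documented constants in `class_color_table()`.
`summarize_trees()` aggregates class counts and canopy totals per row and
per parcel, conserving the tree count.

## Scoring against labeled masks

`score_segmentation()` computes pixel contingency counts with nodata
excluded and reports
$$\mathrm{precision} = \frac{TP}{TP+FP}, \qquad
  F_1 = \frac{TP}{TP + \tfrac{1}{2}(FP+FN)},$$
with recall as a bonus column. Undefined denominators (empty prediction, or
no positives anywhere) are flagged and reported as `NA`, never silently
zeroed. `score_samples()` scores hand-labeled windows individually and pools
them by summed TP/FP/FN (micro-averaging), the natural choice when a few
patches stand in for a parcel.

## The synthetic generator

`generate_orchard()` emulates the study conditions, which are its defaults:
10 rows × 25 trees, 2 m / 6 m spacings, 0.5 m/pixel, crowns as filled disks
with diameters uniform on [1.8, 3] m, a 10% missing/weak rate (diameter 0),
vegetation/soil band means giving NDVI ≈ 0.76 vs ≈ 0.09 (typical
citrus-canopy vs bare-soil contrast), additive Gaussian noise with SD 0.01
(scalar or per-stratum), and a 2 m nodata frame. Disks of neighbors merge
when the diameter exceeds the intra-row spacing, reproducing the
semi-overlap that motivates the method. The default soil margin is 0 m: the
nodata boundary hugs the planted block, as when parcels are clipped by a
polygon drawn tight around the rows. Truth classes are computed by running
the package's own threshold formulas on the true per-box counts, so
"class recovery" compares the full pipeline against the formula applied to
perfect inputs.

Scenes are deterministic given the scenario seed, down to byte-identical
fixture files; band intensities are quantized to 16-bit steps so rasters
round-trip bit-exactly. What the generator does *not* model: crown texture
and within-crown variability, shadows, atmospheric and sensor effects,
curved or irregular rows, and spatially correlated soil. Passing tests on
these scenes demonstrate the geometry and the statistics of the method, not
radiometric robustness on real imagery — the spectral-separation sweeps
(noise raised until vegetation/soil contrast is a few SDs) are the
package's proxy for the latter.

## Numerical and design choices

- **Metric→pixel rounding**: nearest integer, ties half up; monotone in the
  length.
- **Coordinates**: pixels are (row, col), 0-based; geographic lookups use
  pixel centers through a 6-parameter affine geotransform; windows are
  half-open.
- **Raster format**: multiband 16-bit TIFF with a JSON sidecar carrying
  geotransform, resolution, band names, nodata value and CRS text; masks are
  8-bit with nodata = 255. Intensities live in [0, 1]; a pixel is nodata
  when *all* bands equal the nodata value.
- **k-means**: k-means++ seeding, Lloyd iterations (cap 300), 10 restarts,
  fixed default seed; identical seed + input gives bit-identical labels.
- **Degenerate inputs**: constant images yield an all-zero threshold mask
  with a warning; `k` larger than the number of distinct spectra is an
  error; equal counts trigger the degenerate-threshold warning and rule-order
  classification; empty parcels and empty sample lists are errors.
- **Problem sizes**: the test and acceptance suites run on the study-sized
  10 × 25 layout (~125 × 110 pixels) and on 3–6-row miniatures; both
  complete in seconds on one core.

## Limitations

The method assumes a uniform planting pattern; curved rows and irregular
replanting break the lattice model. Anchor quality bounds localization
accuracy on rotated grids. Class thresholds are relative per parcel, so
classes are not comparable across parcels with different vigor. The
weak-vs-missing confound through box overlap is inherent to sampling
overlapping canopy with boxes. Scores on real imagery depend on hand labels
and radiometry that the synthetic scenes deliberately do not claim to
reproduce.
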