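---
title: "Methods: co-registration of elemental maps with histology and region-wise abundance models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-registration of elemental maps with histology and region-wise abundance models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elemap)
```

`elemap` turns two physically incompatible images of the same tissue block —
a pathologist-annotated whole-slide image (WSI) and a destructive elemental
map from a serial section — into one analysis: which annotated structures
carry which elements, and how abundance differs between region groups. This
vignette records the models, conventions and numerical choices behind each
stage, and what the synthetic fixtures do and do not establish.

## Coordinate conventions

One convention is used everywhere and tested everywhere: rasters are
row-major with `(x, y) = (col, row)`, the origin at the top-left pixel,
pixel centers at integer 0-based pixel coordinates, and half-open extents.
The physical position of pixel `(r, c)` is `(c, r) * pixel_size_um`
micrometres. All transforms are estimated and stored in *physical*
micrometre coordinates, never pixels: the two modalities differ 4–40× in
raster scale (≈0.25 µm/px H&E versus 1–10 µm/px elemental), and working in
physical frames decouples estimation from resolution. Pixel↔physical
conversion is exact, so points round-trip between the two raster scales at
machine precision.

## Data model: maps, missingness, storage

An `elemental_map` is a `(rows, cols, channels)` array with unique channel
names, a positive square pixel size, and a parallel logical missing mask.
Missingness is first-class: incomplete ablation, trimmed scan lines and
import gaps are marked, never imputed and never conflated with zero — a zero
is a measured non-detect, a missing pixel is no measurement at all. The mask,
not the `NA` payload, is authoritative, and no operation in the package
converts a missing position into a finite value.

Maps persist in a minimal zarr-v2-layout directory store: one group with a
`data` array of shape `(channel, row, col)`, C order, dtype `<f8`, chunked
`(1, 512, 512)`, uncompressed, plus a `|u1` `missing_mask` array and group
attributes for channel names, pixel size, frame id and units. This is the
smallest layout that round-trips bit-exactly and remains readable by
independent zarr implementations (one test reads the store back through the
Python `zarr` package as a cross-implementation check). Derived rasters
(`tissue_mask`, `region_labels`) attach to the same store. Units of
intensity (counts versus µg/g) are carried as opaque metadata; quantitative
calibration is out of scope.

Channel ingestion accepts one rectangular numeric grid per CSV file or XLSX
sheet, the shape in which acquisition software exports single-element maps.
The dialect is explicit rather than sniffed: `has_header` strips one header
row and one index column when set, because exports vary and silent guessing
is worse than one flag. Ragged rows fail with the offending row number;
empty cells become missing markers. Because the environment provides an XLSX
reader but no writer, the fixture side carries a minimal XLSX writer
(stored-entry ZIP, one sheet per element, absent cells for missing values)
so the Excel dialect can be exercised end-to-end.

## Tissue detection

Tissue on the elemental side is detected by a fixed five-stage chain:

1. **Aggregate** selected channels per pixel (`sum` default, or `mean`).
   Missing entries contribute nothing; a pixel missing in all selected
   channels stays missing.
2. **Pseudo-log** transform, fixed as `log(1 + x)`: compresses the heavy
   right tail of count data while keeping zero at zero.
3. **Gaussian smoothing** (`sigma` in pixels, default 2 — about one ablation
   spot at 1–10 µm/px) by *normalized convolution*: the mask-weighted image
   and the mask are blurred with the same separable kernel (truncated at
   4σ) and divided. Out-of-frame positions are treated exactly like missing
   pixels, which subsumes boundary handling — constants are preserved
   everywhere, there is no edge darkening, and missing pixels neither
   receive nor contribute signal. This one-mechanism treatment was chosen
   over a reflective pad because maps with missing scan lines would
   otherwise need two different exclusion rules.
4. **Threshold**: Otsu by default (between-class variance maximized over a
   256-bin histogram of non-missing values; the exhaustive search over all
   cut points is the test oracle), or a user-supplied fixed value. Missing
   pixels always classify as background. A constant image has no threshold;
   it yields an all-background mask with a warning rather than an error,
   since an all-zero map is a legitimate (empty) input.
5. **Morphological cleanup**, in a fixed order: remove 8-connected
   foreground components smaller than `min_object_px` (default 64 px —
   0.0016 mm² at 5 µm/px, well below any tissue fragment of interest), then
   fill 4-connected background components that do not touch the raster
   border and are at most `fill_hole_px` (default 64). Removing specks first
   prevents them from bridging holes; the 8/4 connectivity pair is the
   standard complementary choice, and a "hole" is required to be enclosed
   (border-touching background is background). The chain applies the
   threshold before morphology also when the threshold is user-supplied.
   Cleanup is idempotent, and the parameters echoed in the returned
   `tissue_mask` reproduce the mask bit-exactly.

Connected components are labelled by iterative minimum-label propagation — a
deterministic, vectorized flood fill with selectable connectivity. It is
implemented in-package because the available image library labels only
4-connected components and has no masked-smoothing semantics; a scalar
BFS flood fill and that library (where connectivities coincide) serve as
independent oracles in the tests.

## Landmark registration

Correspondences are manually placed fiducials, fixed frame (WSI) and moving
frame (elemental map), in micrometres. Three nested model families are
supported:

* **affine** (6 dof, the default): least squares via QR on the design
  `[moving | 1]`; requires ≥ 3 non-collinear pairs. QR is used instead of
  the normal equations to avoid squaring the condition number.
* **similarity** (4 dof) and **rigid** (3 dof): orthogonal Procrustes on
  centered coordinates through the SVD of the 2×2 cross-covariance, with the
  determinant forced to +1 — reflections are *rejected*, because a silently
  mirrored fit is the classic registration failure mode for flipped
  sections; a flipped section must be handled by explicit preprocessing.
  Similarity adds one isotropic positive scale (Umeyama form). Requires
  ≥ 2 distinct pairs.

Affine is the default because "linear" co-registration between serial
sections generally needs the extra shear/anisotropy freedom; similarity and
rigid remain available for degraded landmark sets. Fits are invariant to
landmark order, nest in residual (affine ≤ similarity ≤ rigid), and recover
noiseless transforms to below 1e-8 Frobenius. `registration_error()` reports
per-landmark residuals and RMSE in micrometres. Transforms compose and
invert with frame-id checking, serialize to JSON, and singularity is
rejected at construction.

Image resampling (`resample_image`) pulls a source raster onto a target grid
by sampling at the inverse-mapped pixel centers, with nearest or bilinear
interpolation; out-of-bounds samples take the fill value and are reported in
a missing mask. Label and mask images must use nearest, since interpolating
category codes is meaningless.

## Annotation transfer and rasterization

QuPath-dialect GeoJSON (`FeatureCollection` of Polygon/MultiPolygon, label
from `classification.name`, else `name`, else `"unclassified"`) and ASAP XML
(Polygon annotations, label from `PartOfGroup` else `Name`, vertices ordered
by the `Order` attribute) both parse to the same `annotation_set`.
Coordinates in both formats are WSI pixels at base resolution and are
converted to micrometres on ingest with an explicit pixel size — the
conversion factor is input, never guessed. Non-polygon geometries are
skipped with a warning and counted. Writing produces QuPath-compatible
GeoJSON with `classification.name` set; vertices round-trip to 1e-9.

Rasterization assigns each pixel the id of the **last** annotation in input
order whose filled polygon contains the pixel center — matching the z-order
semantics of annotation tools — under the even-odd rule with holes as
additional rings; uncovered pixels are 0. Containment is strict center
containment with the half-open crossing rule, so boundary pixels resolve
deterministically. Label ids are contiguous integers assigned per label in
order of first appearance and never encode label strings; the raster-to-label
mapping travels in a label table. Under an affine map, polygon area scales
exactly by `|det A|` (shoelace identity), and the rasterized area converges
to the polygon area within `2 · perimeter · pixel_size` as resolution
increases — both are tested.

## Region statistics: the two-part hurdle gamma

Elemental abundance within a region is non-negative, right-skewed, and
zero-inflated (non-detects). The package models pixel values with a hurdle
gamma: a Bernoulli detection part `P(y > 0) = p`, with
`logit p = xᵀγ`, and a gamma abundance part for positives with log-link mean
`log µ = xᵀβ` and shape `k`. Because the two parts factorize the likelihood,
they are estimated separately — logistic and gamma regressions through
`glm`, the shape by Newton iteration on the profile log-likelihood

`log k − ψ(k) = −1 − mean(log(y/µ̂) − y/µ̂)`

with the standard log-moment initialization, converging in a handful of
steps (tolerance 1e-10, cap 50 iterations). Coefficient standard errors come
from the Fisher information (for the log-link gamma part,
`I(β) = k XᵀX`); the shape standard error from the observed information
`n(ψ′(k) − 1/k)`. The total log-likelihood is the sum of both parts and is
verified in tests against a direct evaluation of the hurdle density.
Degenerate inputs set flags instead of failing: no zeros (detection part not
estimable), no positives (gamma part not estimable), exactly fitted
positives (infinite shape), or perfect separation of detection between
groups (odds ratio not identifiable).

`zero_eps` (default 0) defines a non-detect as `value ≤ zero_eps` on
non-missing pixels; missing pixels are excluded entirely, not treated as
zeros. Group comparisons pool the pixels of regions mapped to exactly two
groups, fit the hurdle model with a group indicator (reference = the
alphabetically first group), and report the gamma group coefficient as the
abundance log mean ratio with a Wald p-value, the detection odds ratio, and
Benjamini–Hochberg q-values across the elements of the call — BH across one
invocation is the multiplicity unit because each invocation is one family of
element-wise hypotheses.

Two deliberate simplifications: the model is a frequentist fixed-effects
analogue of hierarchical hurdle-gamma regression — patient-level random
effects are out of scope, so inferences are per-section; and pixel values
are treated as independent within regions, with no spatial autocorrelation
adjustment. Both make the reported standard errors optimistic for strongly
autocorrelated maps; pixel counts, not effective sample sizes, drive them.
Both entry points are provided — pixel vectors (`fit_hurdle_gamma`,
`compare_groups`; the default) and region-level records
(`summarize_regions`) — since either aggregation level can be the right unit
depending on the study.

## The synthetic fixture generator

`fixture_spec(seed)` defines, and `make_fixture()` deterministically renders,
a complete simulated study at the two modalities' native scales
(0.25 µm/px WSI, 5 µm/px elemental, 160×160 elemental grid ≈ 0.8 mm field):

* a circular tissue disc with four disjoint annotated regions (*Tumor*,
  *Stroma*, *Duct*, *Fat* — labels from the breast-pathology vocabulary)
  as regular 32-gons;
* per-region hurdle-gamma abundance (defaults: detection probabilities
  0.5–0.9, shapes 1.5–3, positive means 4–20; the unannotated disc interior
  at detection 0.8, mean 5) over five isotope channels, against a near-zero
  noisy background — separations a well-prepared section would show;
* a ground-truth similarity transform sampled within plausible
  serial-section misalignment (rotation ≤ 15°, scale 0.95–1.05, translation
  20–80 µm per axis);
* landmarks as true correspondences plus Gaussian noise (default sd 1 µm);
* optional missing ablation rows masked in every channel;
* optionally, a rendered WSI raster of the same geometry through the true
  transform (region fills are analytic circles; the sub-micrometre sliver
  between a circle and its 32-gon annotation is cosmetic only).

Both "sections" share identical geometry: true biological section-to-section
drift is not simulated. Passing tests therefore establish the *computational*
chain — ingestion, detection, registration, transfer, statistics — against
known truth; they do not establish robustness to real serial-section
anatomy differences, stain variation, or instrument drift. Realistic H&E
texture and ablation physics are likewise out of scope.

Problem sizes were chosen so each annotated region holds ≈ 2000 elemental
pixels — enough for the 3-standard-error recovery checks to be sharp — and
the whole default suite (including a 1000-replicate null calibration of the
group Wald test at 500 pixels per group, and multi-seed detection/recovery
sweeps) completes in about a minute.

## Command-line interface

The pipeline is exposed as subcommands (`simulate`, `convert`, `detect`,
`register`, `transfer`, `stats`) over plain-file handoffs — no server, no
database — so each stage is independently runnable and replayable. Options
come from `--key value` flags over an optional `--config` YAML (flags win);
unknown keys are rejected by name rather than ignored, since a typo that
silently falls back to a default is the worst failure mode for a batch tool.
Every stage writes a JSON provenance record (resolved configuration, inputs,
package version, timestamp) sufficient to re-run it (`replay_provenance()`),
and identical inputs reproduce byte-identical tabular outputs.

## Known limitations

* Linear (at most affine) registration only: scored, folded or locally
  distorted sections need nonlinear methods that are out of scope.
* No pyramidal WSI decoding; the WSI side is an exported raster level with
  its resolution from the caller or the file's resolution metadata (PNG
  resolution is metre-quantized by the format itself).
* Statistical inference is per-section and ignores spatial autocorrelation
  (see above).
* Otsu thresholding assumes a bimodal aggregate; maps where tissue and
  background intensities overlap need the fixed-threshold path.
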