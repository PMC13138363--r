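---
title: "Granule morphometry and islet composition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Granule morphometry and islet composition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and design decisions behind
`isletmorph`, in the spirit of a methods section: what each stage assumes,
which knobs matter, and what passing the test suite does and does not
establish about real data.

## 1. The measurement problem

Pancreatic islet secretory granules are classified in electron micrographs
by their halo morphology: β-cell granules are roughly 350 nm diameter
vesicles whose crystallized insulin core (electron-dense) sits inside a wide
electron-lucent halo; α-granules show a thin halo; δ-granules none. Granule
*maturity* is read from the contrast between core and halo — a condensed
core sharply separated from a penetrable halo marks a mature granule, and
the **core-to-halo ratio** is the scalar that tracks it. The pipeline's job
is to turn a whole-islet STEM acquisition into per-granule records (class,
area, core/halo decomposition) and per-islet aggregates (counts, densities,
class ratios, mean sizes and ratios).

Because original micrographs are rarely redistributable, the package treats
a synthetic generator with exact ground truth as a first-class module:
every downstream stage is validated by parameter recovery against scenes
whose granule geometry is known to the pixel.

## 2. The synthetic scene model

`scene_params()` describes a scene; `sample_scene()` draws granule
geometry; `render_scene()` paints it.

* **Geometry.** Granules are ellipses with bounded eccentricity (default
  range [0, 0.4]; the hard ceiling of 0.6 keeps instances convex enough for
  distance-transform splitting). Outer radii are Gaussian per class,
  truncated at > 2 px. Defaults at 4 nm/px: β-mature mean radius 175 nm
  (350 nm diameter), α 125 nm, δ 110 nm, β-immature 165 nm. The core is a
  concentric, co-oriented ellipse scaled by a per-granule *core fraction*
  drawn uniformly per class: β-mature 0.55–0.70 (wide halo, fraction
  ≥ 0.25 of the radius), α 0.86–0.90 (thin halo ≤ 0.15), δ exactly 1 (no
  halo), β-immature 0.78–0.94. The α range is kept away from its 0.85 lower
  bound so the thin halo stays ≥ ~2.5 px wide — at 4 nm/px a halo thinner
  than a pixel would be sub-resolution and meaningless to segment.
* **Counts and density.** The default scene is 2048 × 2048 px (8.2 × 8.2 μm)
  with 70 β-mature, 30 α, 15 δ and 5 immature β granules — at least 100
  annotated granules per scene at ~14% area fill, which places comfortably
  under the non-touching constraint. These defaults are the package's
  standing study conditions; tests and the acceptance script use them
  unchanged.
* **Placement.** Rejection sampling with bounded retries. Non-touching mode
  requires a boundary gap of `min_center_spacing` (default 8 px — larger
  than the segmenter's closing diameter, so closing cannot bridge distinct
  granules). `allow_touching` relaxes the constraint to
  d ≥ 0.8·(r₁ + r₂), which caps pairwise overlap near 10% of a granule's
  area and keeps instance ground truth well defined.
* **Intensities.** The electron-dense core renders *bright* (0.9), the
  penetrable halo *dark* (0.1), cytoplasm intermediate (0.45); an `invert`
  flag serves the opposite contrast convention, and the segmenter has a
  matching `polarity` switch. This polarity choice turns "dense core /
  penetrable halo" into a monotone intensity statement the classical
  segmenter can exploit.
* **Immature β granules** are rendered at low contrast (core at 40%, halo at
  20% of the core-cytoplasm contrast above cytoplasm — a pale core with
  indistinct halo separation, consistent with their lesser condensation)
  and are mapped to *background* in semantic ground truth: the segmentation
  contract has only four output classes and immature granules exist to
  stress false-positive behavior. Their pale cores sit safely below the
  global core threshold, so the reference segmenter ignores them by
  construction rather than by annotation.
* **Texture and noise.** Background texture is a Gaussian-smoothed noise
  field (length scale 40 px) scaled to an amplitude capped at 30% of the
  core–halo contrast and applied to cytoplasm pixels only; pixel noise is
  additive Gaussian (sd 0.03). The texture field is synthesized on a coarse
  grid and upsampled — it has no energy above the coarse Nyquist, so this
  equals full-resolution smoothing at a fraction of the cost.
* **Determinism.** All stage randomness derives from the scene seed through
  fixed sub-seeds; identical parameters give bit-identical images and
  ground truth. Realized per-granule core/halo areas are tabulated from the
  final label arrays, so they equal rendered pixel counts exactly even
  under clipping at image borders or paint-over in touching mode.

What the generator does *not* emulate: electron optics, organelles
(mitochondria, ER, nuclei), staining gradients, or real granule shape
irregularity. Passing recovery tests therefore demonstrates the pipeline's
correctness and calibration on histogram-separable images, not robustness
to every real-world artifact; the trainable backend exists for the latter.

## 3. Tiled segmentation

Whole acquisitions are processed as overlapping 2024 × 1024 px tiles
(`make_tile_grid()`), the per-axis stride being tile − overlap with the last
tile clamped to the image edge. The overlap default is 256 px — large
enough that any granule (≤ ~120 px diameter) influencing a kept pixel is
fully visible inside the owning tile. Overlaps are resolved by
**center-crop priority** (each pixel taken from the tile whose center is
nearest, ties toward the lower offset): simpler and deterministic compared
with voting, and it discards border predictions in favor of interior ones.

The reference segmenter (`segment_tile()`) implements the class definitions
directly:

1. Gaussian smoothing, σ = 1 px (just enough to suppress pixel noise
   without erasing thin α halos).
2. **Global two-stage Otsu.** One Otsu split of the whole smoothed
   histogram isolates whichever minority mode lies farther from the
   dominant cytoplasm mode; a second Otsu on the cytoplasm side finds the
   other threshold. Deciding by mass (which side of the first split holds
   the majority) makes the scheme valid whether cores or halos get peeled
   off first. Both thresholds are computed once per image and passed to
   every tile — per-tile thresholds would make output depend on tile
   placement. Since both rendered edges (core→halo, halo→cytoplasm) are
   step edges and Otsu lands near the histogram midpoints, the recovered
   boundaries are unbiased to about half a pixel.
3. Core mask above the core threshold; halo mask below the halo threshold;
   halo components are attached to cores by a 2 px dilation (the blurred
   transition ring between core and halo can otherwise disconnect them);
   candidates are closed (radius 2 px) and hole-filled.
4. Per component, the class follows the equivalent-radius halo fraction
   1 − √(core area / area): ≤ 0.05 → δ ("no halo" needs a numeric
   tolerance under noise), ≤ 0.20 → α, else β. The 0.20 boundary
   interpolates the generator's α (≤ 0.15) and β (≥ 0.25) regimes.
   Components below `min_granule_area` (the area of a 100 nm disk at the
   current scale, ~491 px² at 4 nm/px) are discarded as sub-granule debris.

Degenerate inputs are defined: constant tiles segment to background; a
histogram without a sub-core mode falls back to half the core threshold for
the halo split.

The optional trainable backend (`train_backend()`) is a single-hidden-layer
softmax network over multi-scale Gaussian intensity features, behind the
same tile contract. The hidden layer is essential — granule pixels are
*bimodal* in intensity (core above, halo below cytoplasm), which no linear
pixel classifier can separate. With zero epochs the handle predicts
background and the pipeline still runs, so backend wiring is testable
without training.

## 4. Instance separation

`watershed_split()` runs per class (the semantic classes already partition
the pixels; joint splitting could merge across classes). Per class:
Euclidean distance transform; seed candidates at its local maxima within a
`min_seed_distance` window; deterministic greedy selection ordered by
decreasing depth with ties broken by lowest (row, column); every connected
component keeps at least one seed so no region is silently lost; labels
grow from the seeds within the class mask following the distance topography
(a seeded watershed on the negated distance transform). Defaults:
`min_seed_distance` = 0.6 × the expected β radius (≈ 26 px at 4 nm/px) —
close enough to split overlapping pairs whose centers are ~one radius
apart, far enough not to shatter single granules on distance-transform
plateaus; `min_area` as in segmentation. Both defaults are debris/fragment
policies the source imaging literature leaves unstated, fixed here and
logged in every output.

## 5. Morphometrics

`decompose_core_halo()` thresholds each granule's *own* intensity histogram
(per-granule Otsu), so acquisition-wide shading cannot bias the
decomposition; core and halo partition the granule pixel set exactly, and
δ-class granules take halo = ∅ by definition. Granules with intensity
spread below 0.05 are assigned wholly to core and flagged `low_contrast`
rather than split arbitrarily.

Two deliberately fixed ambiguities, both flagged rather than guessed
elsewhere: **core-to-halo ratio is area-based** (core area / halo area),
and **granule size means area** — a segmentation mask natively yields
areas, and all package outputs stay internally consistent with these
definitions (a diameter-based convention would scale differently).
Ratios with empty halos are `NA` with `ratio_undefined = TRUE`, never 0 or
infinity. Conversions use area_nm² = area_px² × (nm/px)².

`islet_summary()` aggregates to the standard per-islet quantities; ratios
with zero denominators are `NA` plus a flag, and empty record sets
summarize to zero counts without error. When no islet outline is available,
`islet_area_from_mask()` uses the convex hull of all granule pixels — a
stated approximation, since islet delineation conventions vary.

## 6. Composition, AUC, and test dispatch

Marker-call thresholding is out of scope (it is a manual, per-section step
in slide-analysis software); the module starts from per-cell boolean calls.
The positivity rule (≥ 3 insulin⁺ or ≥ 3 glucagon⁺ cells) excludes
non-islet objects before aggregation; exclusions are recorded per islet.
Proportions are normalized to DAPI⁺ nuclei; islets without DAPI⁺ nuclei are
excluded with a logged reason rather than producing 0/0. Because published
tables do not state whether means pool islets or average per animal first,
both aggregations are provided; pooled-per-islet is the default. The
simulation model (cell-type mixture × conditionally independent marker
emissions) has closed-form profile proportions, giving the estimator a
convergence oracle.

AUC is the composite trapezoid over the measured grid; *total* AUC is the
default, with the incremental (baseline-subtracted) variant exposed, since
conventions differ and the choice changes group contrasts when baselines
differ.

The dispatch module fixes the gate level at α = 0.05 for Shapiro-Wilk and
the variance gates (the convention states the tests, not the gate level;
p ≤ α counts as significant, matching the usual reporting convention). The
two-group variance gate is the F-test; for ≥ 3 groups the median-centered
Levene test replaces pairwise F-tests for robustness. Tamhane T2 is
implemented from its definition (pairwise Welch t with Šidák-style
correction 1 − (1 − p)^m) and Dunn's test from pooled tie-corrected ranks
with Bonferroni adjustment, as neither has a canonical implementation among
the package's dependencies; both are validated against hand-computed
examples and rank-invariance properties. Groups with n < 3 skip the
normality gate (Shapiro-Wilk is undefined there) and fall back to the
nonparametric path, flagged. Degenerate zero-variance samples are treated
as non-normal.

## 7. Pipeline reproducibility

`run_pipeline()` derives every stage seed from one top-level seed, writes
per-scene and per-cohort tables, the dispatch report, and a manifest with
the configuration hash; rerunning a configuration reproduces outputs
bit-exactly. Configuration validation happens before any compute, so a
missing image path fails fast.

## 8. Problem sizes used by the test suite

The suite validates invariants at sizes chosen to exercise every code path
while remaining desk-scale: tiling round-trips on twenty 2600 × 1300 px
scenes; parameter recovery on twenty default 2048² scenes (counts, mean β
area and mean β core-to-halo each within 5% of ground truth, pooled over
scenes); the core-condensation direction on ten seeds (0.5 vs 0.7 core
fraction); a twelve-scene two-cohort demo; 2000-replicate type-I
calibration of the dispatch at n = 20 per group; 1000 simulated islets for
the composition identities. The acceptance script reruns the same
computations at slightly reduced scene counts and reports the measured
quantities as JSON.

## 9. Known limitations

* The classical segmenter assumes a three-mode intensity histogram; heavy
  shading, montage seams, or organelle clutter break that assumption
  (use the trainable backend with annotated tiles).
* Ellipse granules understate real shape irregularity; recovery results
  quantify algorithmic correctness, not biological variance.
* The watershed uses geometric (distance) evidence only; intensity-guided
  marker-controlled splitting is out of scope.
* Area-based core-to-halo ratios are not numerically comparable to
  diameter-based ones; comparisons across studies must check conventions.
* 3D stacks, multi-islet stitching and spectral unmixing are out of scope.
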