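---
title: "From annotated slides to abstaining diagnoses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From annotated slides to abstaining diagnoses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidediag)
```

## The pipeline

slidediag turns annotated whole-slide images (WSI) of prostate tissue into
patch-level training data and scan-level diagnoses. The stages are:

1. **Hierarchical patch labeling.** Pathologists outline regions on a scan
   and assign each one of nine classes: scan background (`BG`), tissue
   background (`T`), normal tissue (`N`), artifact (`A`), or a Gleason grade
   `R1`–`R5`. Patches of 256×256 px are taken on a stride-128 lattice at
   four pyramid levels (40×, 20×, 10×, 5×). A 40× patch receives a label iff
   exactly one class covers at least 75% of its area (boundary inclusive);
   zero qualifying classes, or two or more (possible only with overlapping
   regions), leave it unlabeled. A lower-magnification patch is subdivided
   into the 4, 16 or 64 non-overlapping 256-px 40×-level squares tiling its
   physical footprint; each is labeled by the 40× rule, and the **most
   severe** labeled value wins (`N, R3, R3, R4 → R4`). Severity is the total
   order `BG < T < N < A < R1 < … < R5`; only cancer-over-non-cancer
   dominance is medically meaningful, and the non-cancer portion of the
   order is configurable.
2. **Valid-tissue segmentation** on an 8×-downsampled image restricts
   classification to tissue (default: multi-level Otsu, see below; a small
   fully convolutional network is the alternative).
3. **Patch classification** produces, per scan and magnification, a
   *probability map*: one class-probability vector per grid cell. The
   classifier is pluggable; the package ships a deliberately small
   reference backbone (softmax regression on mean-color features) so the
   whole pipeline runs on a desk. Deep backbones are configuration, not
   code.
4. **Ensembling** combines maps across architectures and magnifications by
   rescaling to the coarsest grid (block-averaging probability vectors,
   which is linear and stays on the simplex) and arithmetic averaging,
   optionally followed by median filtering of the binarized map.
5. **Scan-level diagnosis.** The statistic `p_c` is the percentage of valid
   tissue cells whose call is cancerous; the abstaining rule outputs
   `NC` if `p_c ≤ T_L`, `C` if `p_c ≥ T_U`, and `IHC` (abstain, further
   examination) otherwise. `threshold_sweep()` maps the accuracy/coverage
   trade-off over a grid of `(T_L, T_U)` pairs.
6. **Rater agreement.** Ordinal encoding `NC < IHC < C` and tie-corrected
   Spearman correlation (Pearson of mid-ranks) quantify pairwise agreement
   between human raters and the automated rule.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| patch size / stride | 256 / 128 px | level pixels | half-overlapping grid; edge patches are dropped, not padded |
| overlap threshold | 0.75 | fraction | labels only clearly dominated patches |
| binarization setting | `S1` (`R1`–`R5` cancerous) | — | `S2` treats `R1`/`R2` as non-cancerous; grades 1–2 are rarely reported clinically |
| tissue downsampling | 8× | — | segmentation operates at ~2 µm/px |
| patch-validity rule | ≥ 50% tissue footprint | fraction | couples the pixel mask to the patch grid; configurable |
| `T_L`, `T_U` | 0.5%, 7% | percent of `p_c` | reference operating point of the abstaining rule |
| sweep grids | `T_L ∈ {0,…,2}`, `T_U ∈ {2,…,15}` | percent | spans the operating range where the two diagnoses overlap |
| median filter kernel | k = 3 | cells | removes isolated false calls without erasing clusters |
| classifier schedule | 50 epochs SGD, lr 1e-4, ×0.1 every 20, batch 32, wd 5e-4 | — | reference schedule for deep backbones; the tiny reference backbone needs a larger lr (overrides are logged) |
| FCN architecture | 10 conv layers × 64 3×3 filters, 600 epochs Adam lr 1e-4 | — | reference segmentation network; tests train reduced configurations |

## Numerical and design choices

**Exact coverage geometry.** Patch coverage is computed by exact polygon
geometry, not rasterization: a scanline decomposes the patch into
horizontal slabs at every event *y* (polygon vertices, pairwise edge
crossings, and crossings of the patch's vertical borders — the last are
needed because clipping kinks the interval length). Within a slab the
union of x-intervals has fixed structure and linear endpoints, so
mid-slab length × height is exact. This handles overlapping same-class
regions without double counting and needs no clipping library. The
pixel-rasterization computation exists only as an independent test oracle.

**Multi-level Otsu.** A scan whose tissue spans several stain intensities
has a *tri-modal* gray histogram, and classic two-level Otsu can place its
threshold between tissue modes, discarding pale tissue wholesale. The
default therefore computes an exhaustive 3-level Otsu split of the 256-bin
histogram and keeps the threshold adjacent to the bright background mode;
on bimodal input this coincides with classic Otsu (available as
`levels = 2`). A 3×3 morphological closing fills pinholes. A constant
image yields an all-background mask with a warning.

**Inference crop.** Classifiers consume 224×224 inputs while the grid
stores 256-px patches; evaluation takes the central crop at offset
(16, 16), keeping exactly one map cell per grid position. Training mode
crops randomly and adds horizontal flips and 90° rotations, with all
randomness drawn from R's RNG so a seed reproduces runs bit-exactly.

**Ensemble grid mismatch.** Patch grids at different magnifications are
not exact integer multiples of one another (the grid loses a partial row
at the scan border), so `run_ensemble()` trims trailing rows/columns of
the finer map to the largest integer multiple of the target before
pooling. `rescale_map()` itself rejects non-integer ratios.

**Median-filter ties and borders.** Filtering runs on the binarized
cancer map with reflection padding; cells outside valid tissue are
excluded from every neighborhood and left unchanged. With exclusions a
neighborhood can have even size; a tie keeps the cell's own value. One
filter application is *not* idempotent in general — thin structures keep
eroding — but iteration reaches a fixed point within a few steps; the
test suite asserts convergence, complement-equivariance and monotonicity
rather than one-step idempotence.

**Labeling is not monotone under overlap.** Adding a cancerous region on
top of an already-labeled patch can raise a *second* class above the 0.75
threshold, which the rule treats as contradictory, unlabeling the patch.
Severity monotonicity therefore holds only for regions added on
previously unannotated tissue, and that is the property the suite tests.

**`p_c` denominator.** Valid cells whose argmax class is `BG` are removed
from the denominator along with segmentation-excluded background, so
`p_c` is a fraction of actual tissue. An empty denominator makes `p_c`
undefined; the rule then abstains with a warning.

**Agreement reporting** rounds half away from zero to 2 decimals, the
precision such tables are conventionally reported at; the matrix itself
is stored at full precision.

## The synthetic-data generator

`generate_scan()` lays non-overlapping axis-aligned rectangles (snapped
to 8-px multiples so the 1/8-resolution truth mask is exact) over a white
background at 40× and renders the lower levels by block-averaging. Class
textures are separated by *mean color* on purpose so the reference
backbone can learn them; the default class mix follows published
annotation-class frequencies over the non-background classes, and region
sides default to 128–384 px, the scale of annotated lesions at 40×.
`generate_probability_map()` grows one 4-connected cancer blob covering a
requested fraction of cells and draws each cell's vector from a Dirichlet
concentrated on its true class (`alpha = sharpness` on the truth, `1/K`
elsewhere); as sharpness grows, the argmax map converges to the truth.
`generate_cohort()` samples `p_c` from two log-normals (non-cancerous
mass near zero, cancerous mass in the tens of percent, prevalence
2090/4675), emulating the bimodal screening-cohort structure with an
ambiguous overlap that makes abstention worthwhile.

What the generator does **not** emulate: stain variation, texture (classes
differ only in color statistics), irregular region shapes (rectangles by
default), blur, pen marks or other artifacts. Tests passing on synthetic
scans therefore demonstrate the correctness of the machinery — geometry,
bookkeeping, statistics — not clinical performance of any classifier.

## Problem sizes

The test suite and acceptance script run on deliberately small instances:
scans of 512–1024 px at 40×, 3–8 regions, cohorts of 100–500 scans,
probability maps up to 32×32 cells, and reduced classifier/FCN
configurations (e.g. 8 epochs at lr 0.5 for the mean-color backbone;
3 conv layers × 8 filters for the FCN). These sizes were chosen so that
every stage, including end-to-end scan diagnosis on 20 scans, completes
in minutes on one CPU while leaving the algorithms identical to the
full-scale configuration.

## Known limitations

* The published pairwise agreement table is not fully reproducible from
  the published per-scan diagnosis table: coefficients involving raters
  D1, D4 and the automated rule deviate by 0.01–0.03 under every
  correlation variant examined (tie-corrected or not, alternative
  encodings, row subsets). The package reports the values computed from
  the packaged per-scan table.
* Native readers for proprietary WSI formats (NDP/NDPI, DICOM-WSI) are
  out of scope; pyramids are read from per-level PNG images, annotations
  from GeoJSON.
* The FCN trains on CPU in pure R; it is desk-scale by design. Deep
  backbones plug in through the three-function backbone contract.
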