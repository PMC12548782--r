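---
title: "Quantifying ER remodeling in single cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ER remodeling in single cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ermorph)
```

## The measurement problem

Epithelial cells reorganize their endoplasmic reticulum under stress:
membranes that are normally concentrated around the nucleus spread toward
the cell periphery, and the fine texture of the peripheral ER (tubules vs.
sheet-like or pitted regions) changes with it. `ermorph` turns multi-channel
2D fluorescence fields into per-cell numbers that capture this remodeling,
and per-plate screen statistics that rank perturbations against controls.

The core quantity is the **expansion ratio**: the mean ER-marker intensity
in a peripheral cytoplasmic band divided by the mean in a perinuclear band.
Because it is a ratio of means over regions defined at *relative* distances,
it is invariant to overall staining intensity and — by construction of the
radial coordinate — insensitive to cell size and shape.

## The normalized radial coordinate

For each cytoplasmic pixel $p$ we compute the Euclidean distance
$d_{nuc}(p)$ to the nucleus mask and $d_{edge}(p)$ to the complement of the
cell mask, and set

$$d_n(p) = \frac{d_{nuc}(p)}{d_{nuc}(p) + d_{edge}(p)} \in [0, 1].$$

$d_n$ is 0 on the nuclear boundary and 1 on the cell edge, whatever the
local nucleus-to-edge span. The perinuclear band is $d_n < f_{PN}$ and the
peripheral band $d_n > 1 - f_{PE}$. Both fractions default to 0.25
(dimensionless; config-exposed), giving two clearly separated bands with an
uncommitted middle zone — wide enough that small segmentation errors at
either boundary do not move pixels across bands, narrow enough that each
band has a distinct radial identity. Nuclear pixels carry no radial value,
so the perinuclear band starts at the nuclear boundary and never leaks into
the nucleus.

Two numerical points matter:

* **Half-pixel correction.** Distance maps return center-to-center
  distances, but the true mask boundary runs between pixel centers. We
  subtract 0.5 px from both distances (clamped at 0). Without this, $d_n$
  carries a scale-dependent bias and the band areas drift by several percent
  when the same cell is rendered at twice the size; with it, band area
  fractions agree within 2% across a two-fold size change and the measured
  expansion ratio within well under 1%.
* **Degenerate cells.** If the cytoplasm is too thin to populate both bands
  (or the perinuclear mean is zero), the cell's features are returned as
  `NA` with `feature_valid = FALSE` and the cell is excluded from
  aggregates — never silently zeroed.

## Texture: ridge and hole kernels

ER tubules at this resolution appear as ~1-px bright curvilinear ridges;
pitted/fenestrated regions as 1-px dark holes. We score both with zero-mean
3×3 matched filters: second-derivative line kernels at 0°, 45°, 90°, 135°
(per-pixel response = max over orientations) and a center-surround
dark-center kernel. Scores are the mean *positive* response over the cell
mask, normalized by the cell's mean ER intensity — dimensionless, zero on a
flat image, and invariant to intensity scaling.

The hole kernel uses the 4-connected surround with a gain of $1/2.5$ rather
than the 8-connected mean-difference form. The reason is a cross-talk
budget: the pixels flanking a 1-px dark pit legitimately excite the line
kernels (locally they *are* bright ridges next to the pit), and one can show
that with the 8-surround kernel no single gain lets a pit fixture win on the
hole channel while a line fixture wins on the ridge channel — the two
crossover gains coincide. The 4-neighbor kernel separates the two regimes;
the bundled fixtures discriminate with ~1.1–1.3× margins in both directions.
We implement the mean-response variant of the score; a thresholded-fraction
variant would be a straightforward alternative but is not currently exposed.

## Segmentation and QC

Nuclei: Gaussian smoothing (default σ = 2 px), Otsu or fixed threshold,
connected components, optional distance-transform watershed to split
touching nuclei, minimum-area filter (80 px²). Cells: seeded region growing
(`EBImage::propagate`) of the above-threshold cytoplasmic foreground from
the nuclear seeds, so cell labels inherit nucleus labels, every cell
contains its nucleus, and two nuclei sharing one foreground blob split along
the (intensity-weighted) equidistance boundary; a purely geometric
nearest-seed mode is available. A nucleus falling outside the foreground
keeps a cell equal to its own footprint, with a warning.

QC emits three flags per cell, any of which excludes it from well
aggregates: border contact, area outside `[400, 50000]` px², and
out-of-focus. The focus score is the variance of the 3×3 Laplacian of the ER
channel within the cell mask divided by the squared mean intensity. On the
synthetic fixture family, sharp textured cells score ≳ 0.2 and cells blurred
with σ ≥ 3 px score ≲ 0.006 — a >30-fold gap — so the shipped threshold of
0.04 (calibrated once on those fixtures, near the geometric midpoint) is not
delicate. Real images will need recalibration through the config; the
threshold is a parameter, not a constant of nature.

## Protrusions and the polarity index

The cell body is the morphological opening of the mask with a disc
(default radius 8 px at 0.65 µm/px — large enough to remove neurite-scale
arms, small enough to preserve the soma); protrusions are connected
components of the remainder above 20 px². Manually segmented protrusion
masks, when provided, take precedence — automated decomposition is the
reproducible default, manual masks the authoritative path.

Protrusion length is the within-component geodesic distance from the
attachment zone (pixels touching the dilated body) to the farthest pixel,
plus 1 px because a run of $n$ pixels spans $n$ pixels while center-to-center
distances span $n-1$. Orientation is the vector from the attachment centroid
to the centroid of the geodesic tip region (averaging over the tip region
keeps angles stable for blunt tips). On rectangular-arm fixtures, lengths are
recovered within ~1 px and the polarity index within 0.02 of its closed form.

The polarity index is

$$P_i = \frac{\sum_i (1 - |\sin \alpha_i|)\, L_i}{\sum_i L_i},$$

with $\alpha_i$ the angle between protrusion $i$ and the longest protrusion.
The sum includes the longest protrusion itself ($\alpha = 0$, weight 1), so
a single-protrusion cell scores exactly 1 — we treat this as the natural
reading of the formula and flag it as a convention. Because only
$|\sin\alpha|$ enters, the measure is axial: an antiparallel protrusion
(180°) counts as aligned. Exact length ties resolve to the lowest component
index; this is deterministic and, because of axiality, does not change
$P_i$. The relative largest-protrusion length is $\max_i L_i$ divided by the
body's moment-based major axis.

## Assay readouts

* **Spots (PLA).** White top-hat (disc radius 4 px) enhancement, threshold
  at median + 5·MAD of the enhanced image, area filter `[2, 90]` px²,
  assignment to the cell containing the centroid. Integrated signal sums
  intensity above the local background, the median in a 2-px annulus around
  each spot — insensitive to neighboring spots. The MAD is floored at 1% of
  the enhanced dynamic range so that an exactly noise-free background (MAD
  = 0) still yields a meaningful threshold; the floor scales with the image,
  preserving intensity-scale invariance of counts.
* **Transwell.** Each side's image is Otsu-segmented; the readout is the
  total above-background (median of the non-foreground) signal on the basal
  (trans) side divided by the top (cis) side.
* **3D invasion.** Percent migrated = 100 × (nuclei at the plate bottom) /
  (total over bottom + elevated planes). Cells invade the gel toward the
  plate, so "migrated = bottom" is the default convention; the opposite
  convention is available and stamped on the result, since the assignment
  of compartments depends on the seeding geometry.

## Screen statistics

Per-well summaries (mean and median per feature over QC-passing,
feature-valid cells) feed control-referenced Z-scores per plate and feature:
$Z = (s - \bar{s}_{ctrl}) / \mathrm{sd}(s_{ctrl})$, with the $n-1$
denominator, the well mean as the default statistic (median available), and
condition entries averaging their wells' Z. Zero control SD produces a
flagged `NA`, never ±∞. One caution we document rather than hide: with $m$
control wells the null variance of $Z$ is $(1 + 1/m)(m-1)/(m-3)$, so with
few controls (e.g. $m = 8$) null Z-scores have SD ≈ 1.25, not 1. Our tests
verify unit spread at adequate control counts and the theoretical inflation
at small ones; screens with few controls should interpret |Z| thresholds
accordingly.

Replicate comparisons use the classic pooled-variance two-sample Student
t-test (Welch as an option), two-tailed, with stars at p < 0.05 / 0.01 /
0.005 and no multiple-testing correction by default (a Benjamini–Hochberg
step can be applied downstream via `p.adjust`; we report raw p-values as
screen figures conventionally do). Condition profiles are clustered with
average linkage on 1 − Pearson distance (Euclidean available); rows with
undefined entries are dropped or mean-imputed per config, the leaf order is
the deterministic `hclust` order, and the dendrogram exports as Newick.

## The synthetic data generator

The generator is first-class, tested code — it defines the conditions every
downstream claim is verified under. Cells are smooth star-convex blobs
(a disc radius modulated by 3 low-order cosine harmonics, amplitudes ≤ 0.04)
with one elliptical nucleus each, placed by rejection sampling with no
overlap; an over-full request fails with an explicit capacity error. The ER
channel is painted piecewise-constant over the same normalized radial
coordinate the pipeline measures: perinuclear level $2(1-p)\cdot 20000$,
peripheral level $2p\cdot 20000$, intermediate zone at the midpoint, where
$p$ is `er_peripheral_fraction` — so the true expansion ratio is the known
quotient of painted band means (recorded *after* texture overlays and
background, *before* blur and noise, restricted to in-field pixels for
border-clipped cells). Ridges are 1-px random-walk polylines (+0.8× base
intensity); holes are 1-px pixels dimmed to 10%; spots are Gaussian PSF
stamps (σ = 1.2 px, 25000 counts) placed with ≥ 7 px separation — closer
diffraction-limited spots would not be resolvable as two objects at this
kernel scale, so the generator only produces resolvable configurations.
Defocused cells are blurred with a Gaussian (default σ = 3–4 px) before
compositing; Poisson noise (scaled by `poisson_scale`, default 4 counts)
then additive Gaussian read noise (default SD 25 counts) are applied last,
after all ground truth is recorded. Intensities are integer counts in a
16-bit range; acquisition defaults (16-bit, 0.65 µm/px) are configurable
conventions, not claims about any particular instrument.

What the generator does **not** emulate: real ER texture statistics beyond
the two-band + ridge/hole idealization, uneven illumination, spectral
bleed-through, touching/overlapping cells, mitotic or apoptotic
morphologies, and 3D defocus structure. Passing tests therefore demonstrate
that the measurement chain is *correct and invariant where it claims to be*,
not that segmentation would reach the same fidelity on arbitrary real
images — on the synthetic fields segmentation is near-perfect by design, so
the recovery tolerances (3% noise-free, 10% median under default noise)
exercise the radial-band measurement, not segmentation robustness.

## Problem sizes and determinism

The bundled test and acceptance runs use one 1024×1024 px field with 50
cells for recovery/fidelity checks, 512×512 px fields with 6–10 cells for
grids and invariances, a 9-point peripheral-fraction grid, 10,000-replicate
t-test null simulations, and 100 seeded clustering runs — sizes chosen so
the full suite completes in a couple of minutes while keeping Monte-Carlo
error comfortably inside each assertion's margin. All randomness flows from
a single seed through derived per-field seeds; identical spec + seed
reproduces every array bit for bit, and `run_pipeline` rerun with the same
config yields byte-identical tables (each stamped with the config hash).

## Known limitations

* Single focal plane only; no 3D segmentation, stitching, or time series.
* Thresholding is global per field; strong illumination gradients would
  need a background model (an optional field-level background estimate is
  the natural extension; ratio features are already scale-invariant).
* The texture scores are summary statistics, not a tubule/sheet
  reconstruction; they rank conditions but do not measure tubule geometry.
* The focus threshold and spot-detection parameters are calibrated on the
  synthetic fixture family and must be recalibrated for real acquisitions.
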