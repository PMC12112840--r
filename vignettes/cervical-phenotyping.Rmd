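---
title: "Methods: measuring and phenotyping cervical sagittal alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring and phenotyping cervical sagittal alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervimorph)
```

## Scope and model

`cervimorph` works from *annotations*, not images: each lateral cervical
radiograph is represented by labeled polygon outlines of the C3–C7
vertebral bodies in pixel coordinates (x rightward, y downward). C2 is
deliberately absent — the measurement chain is referenced to C3
throughout, so the lordosis and SVA here are C3-referenced variants of the
conventional C2–C7 quantities and are not directly comparable across
studies that use C2.

Four parameters are computed per radiograph:

* **SVA**: horizontal offset of the C3 polygon centroid from the vertical
  plumb line through the posterosuperior corner of C7. Signed; positive
  means the C3 centroid lies anterior to the plumb line.
* **Lordosis**: Cobb angle between the C3 inferior and C7 superior
  endplate lines, normalized to (−90°, 90°]; positive = lordotic.
* **Vertical length**: absolute y-difference of the C3 and C7 centroids.
* **Curved length**: sum of Euclidean distances between consecutive
  centroids C3→C7. By the triangle inequality this can never fall below
  the straight C3–C7 distance, hence never below the vertical length —
  an invariant the tests exercise on random configurations.

### Landmark detection

Endplate anchor points are *band extremes*: the contour is split by its
x-extent, and within the leftmost (or rightmost) fraction
`band_fraction` the lowest (max y) or highest (min y) point is taken.
One extreme point per side cannot define a line, so each endplate line is
the segment joining the extremes of *both* horizontal bands — the lowest
pair for the C3 inferior plate, the highest pair for the C7 superior
plate. This is the minimal completion of a single-anchor band rule into a
tangent line, and for rectangular vertebral bodies it returns the exact
endplate corners.

Ties inside a band are broken by smaller x, then smaller point index, so
landmark detection is deterministic.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `band_fraction` | 0.25 | band width as a fraction of the contour's x-extent, in (0, 0.5]. 0.25 keeps anchor points near the vertebral corners while ignoring mid-plate irregularities. |
| `anterior_side` | `"right"` | radiograph laterality. Acquisition conventions differ and the data carry no flag, so it is explicit configuration. It sets the SVA and Cobb signs and selects the posterior band for the C7 corner. |
| `contour_source` | `"polygon_direct"` | `polygon_direct` uses the annotation polygon itself as the contour (exact); `raster` rasterizes to a binary mask and traces its boundary, reproducing a pixel-level pipeline. |
| `pixel_spacing` | 1 | length units per pixel; all lengths are reported in pixels by default (see *Units*). |

### Units

All lengths are generic pixel units. Cohort-scale vertical lengths of
450–650 for a five-vertebra cervical segment are anatomically implausible
as millimetres (a C3–C7 segment spans roughly 60–90 mm), so published
values at that scale are treated as pixel measurements regardless of the
unit label attached to them; `pixel_spacing` converts to physical units
when a calibration is available.

## Raster path numerics

The raster path fixes an explicit pixel model: cell `(i, j)` is foreground
iff its center `(i+0.5, j+0.5)` is inside the polygon under the even-odd
rule, with boundary points counting as inside. Contours are traced with
Moore-neighbor following (clockwise, started at the topmost-leftmost
boundary cell, Jacob's stopping criterion) and reported as pixel-center
coordinates. Masks with multiple 8-connected components are rejected as
ambiguous; single-pixel masks yield a flagged degenerate contour.

Rasterization quantizes landmarks to the pixel grid, so raster-mode
measurements carry ~1 px positional and ~1° angular error at the body
sizes used in the tests (rectangles of 180 × 120 px in a 1000 × 1400 px
frame); the test suite asserts agreement with the exact polygon-direct
path within 1.5 px / 1.5°. `polygon_direct` is the default because the
annotation polygon is the ground truth the mask merely approximates.

## Synthetic data

Two generators make every stage testable without restricted data.

**Parameter cohorts.** `table1_config()` carries the published
per-cluster summary statistics of the reference DCM cohort (sizes
703/387/228; per-cluster mean ± SD for all four parameters);
`simulate_cohort()` draws each parameter independently from
`Normal(mean, sd²)` within each cluster and shuffles the rows. Only
marginal moments are published, so independence is the minimal
assumption; real radiographic parameters are correlated (longer spines
have longer curved lengths), which is why simulated multivariate cluster
geometry — and therefore any validity index computed on it — need not
match values estimated on the real cohort. Passing cluster-recovery tests
on this fixture shows the pipeline recovers *this* generative structure,
not that real DCM cohorts contain exactly three Gaussian clusters.

**Spine annotations.** `generate_spine_annotation()` builds five
rectangular vertebral bodies whose tilts increase in steps of
`lordosis/4` from −L/2 (C3) to +L/2 (C7), so the two endplate lines
subtend exactly the configured Cobb angle. Body centers follow the arc
with a uniform horizontal shear chosen in closed form so the configured
SVA is met exactly; vertical and curved lengths then follow analytically
from the step vectors. With `lordosis = 0, sva = 0` the bodies are level
and the C3 centroid sits exactly on the C7 plumb line (which requires a
small posterior shear of the centers — truly stacked rectangles would
have SVA equal to half the body width). `generate_cohort_annotations()`
inverts the construction per sampled tuple: vertical steps of V/4, total
horizontal drift fixed by the SVA, and an alternating horizontal zigzag
amplitude solved by `uniroot` so the chord sum equals the requested
curved length (infeasible tuples — curved below the straight chord — are
rejected). Rectangles are geometric phantoms, not anatomy: no endplate
curvature, osteophytes, occlusion or annotation noise are modeled, so
closure tests validate the measurement operators, not robustness to
imaging artifacts. An optional vertex jitter (`jitter_px`) exists for
exploratory use; ground truth refers to the unjittered construction.

## Clustering

Parameters are z-scored with the sample (n−1) SD. k-means uses
k-means++-style seeding, 10 restarts, and Lloyd iterations until the
maximum centroid shift is below 10⁻⁶ (cap 300); restarts that empty a
cluster are re-seeded. `scan_k()` (default k = 2…8) additionally
warm-starts each k with the previous solution's centers plus the farthest
point, which guarantees a non-increasing WCSS curve. All randomness is
funneled through one integer seed.

The feature space for clustering is configurable because the two natural
readings — cluster on PCA scores vs. cluster on the standardized
parameters with PCA used only for visualization — lead to different
pipelines. The default is the standardized four-parameter matrix
(`feature_space = "standardized"`), with `"pca_scores"` selectable; PCA
scores are always computed for plotting either way.

Model selection offers `silhouette_max`, `elbow_knee` (the k at maximal
perpendicular distance from the WCSS curve to its end-to-end chord), and
`manual`. On the reference-style simulated cohort the silhouette
maximum typically lands at k = 2 — the three generating Gaussians overlap
substantially — so reproducing the three-phenotype solution is a `manual`
k = 3 choice on this fixture, mirroring how elbow ambiguity between
candidate k values is resolved by inspection in practice. With k = 3
forced, adjusted Rand agreement with the generating labels is above 0.5
(a smoke bound for overlapping clusters, checked at a fixed seed) and the
three phenotype names are always recovered.

Phenotype naming is statistic-driven, not index-driven: highest mean
lordosis → *normal*; of the rest, longer mean vertical length →
*long-neck*; remainder → *forward-head*. For k ≠ 3 generic names are
returned.

## Statistics

`anova_oneway_raw()` delegates to `stats::oneway.test(var.equal = TRUE)`
after resolving degenerate cases explicitly (zero within-variance gives
F = 0 for equal means, a flagged infinite F otherwise).
`anova_oneway_from_summary()` computes the identical decomposition from
(n, mean, SD) triples — an algebraic identity the tests verify to 10⁻¹⁰ —
which is what allows published summary tables to be audited without raw
data. Reconstructed F statistics inherit the rounding of the printed
summaries: the reference cohort's SVA, vertical-length and curved-length
rows reproduce within 0.5 %, while its lordosis row cannot be reconciled
to better than ~1.5 % from the rounded cells and is therefore checked
only for order of magnitude.

"Bonferroni post hoc tests" underdetermines the pairwise statistic, so
both variance models are provided. Welch (per-pair SE with
Welch–Satterthwaite df) is the default because it reproduces the
published marginal pairwise p values (0.079 and 0.135 for the
vertical/curved length cluster 1 vs 2 comparisons); the pooled-MSW
variant is retained as an option. Adjustment is `min(1, 3p)` for three
clusters via `stats::p.adjust`. The table writer renders p below the
display precision as `<0.01`.

## Problem sizes and test design

The test suite builds all fixtures in code: simulated cohorts of 1318
rows, closure grids over lordosis {0, 8.3, 13.9, 24.1}° × SVA
{0, 70.6, 95.9, 135.6} px, 20-spine end-to-end closure sets, 20-point
instances for brute-force oracle comparisons of the validity indices
(10⁻⁹ agreement), and n ≤ 8 instances where k-means is checked against
the exhaustive-partition optimum. These sizes keep the full suite under
a minute while leaving every numerical claim oracle-backed.

## Known limitations

* C3-referenced metrics; no C2, intervertebral angles, disk heights or
  K-line quantities.
* The independence assumption of the cohort simulator bounds how closely
  simulated F statistics or validity indices can track values estimated
  on the real, correlated cohort — dataset-dependent quantities (specific
  validity-index values, k-scan curve shapes, cluster membership counts)
  are out of reach by construction.
* The published cohort's own cluster sizes sum to 1318 while its reported
  sample is 1371; the generator emulates the printed per-cluster sizes.
* The native annotation JSON schema is this package's own; an adapter for
  other annotation dialects is intentionally out of scope.
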