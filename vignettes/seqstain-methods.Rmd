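---
title: "Methods: sequential IHC registration, quantification, and paired cohort statistics"
author: "seqstain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential IHC registration, quantification, and paired cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqstain)
```

# Scope

Sequential (multiplex) chromogenic immunohistochemistry stains one tissue
section repeatedly: stain one marker, scan, destain/strip, stain the next.
Because every staining/destaining cycle can translate, rotate, and slightly
dilate or shrink the tissue, images from different rounds must be
co-registered before per-cell marker states can be combined into phenotypes
(e.g. GZMB^+^CD8^+^ activated cytotoxic T cells). `seqstain` implements that
pipeline end to end:

1. landmark-based least-squares registration of rounds (`registration`),
2. conversion to optical density and stain deconvolution (`stain
   deconvolution`),
3. nucleus-driven positive-cell detection and density/percentage summaries
   inside annotated tumor regions (`cell quantification`),
4. cross-round mutual-nearest-neighbor cell matching and phenotype counting
   (`co-expression`),
5. the paired-cohort statistical layer: exact Wilcoxon signed-rank test,
   Spearman correlation, descriptives, treatment-group stratification
   (`cohort statistics`), and
6. a deterministic synthetic slide/cohort generator providing ground truth
   for all of the above.

A packaged cohort fixture — a table of 16 metastatic-melanoma patients with
pre- and post-vaccination PDL1 percent positivity and CD8 density ratios —
drives the worked example and the `reproduce_table1_stats()` report.

# Registration

## Model

Rounds are related by a similarity transform (uniform scale $s > 0$,
rotation $\theta$, translation $t$), the smallest family that captures
rigid slide placement plus isotropic tissue dilation/shrink; an affine
model is available for anisotropic deformation. Transforms are 3x3
homogeneous matrices over 0-based, pixel-centered coordinates (x right,
y down) — one convention used everywhere, including polygons and cell
centroids.

Given corresponding reference marks $m_i \leftrightarrow f_i$ (at least 2
for similarity, 3 non-collinear for affine), `estimate_transform()` returns
the *global* minimizer of $\sum_i \lVert T(m_i) - f_i \rVert^2$: the
closed-form Procrustes/Umeyama solution for similarity (reflections are
excluded by forcing the rotation determinant positive — physical slides do
not mirror), and the normal equations for affine. Degenerate configurations
(coincident points; collinear points for affine) are errors, not warnings.

## Fine alignment

`refine_transform()` refines an initial transform without landmarks by
deterministic coordinate descent on $(s, \theta, t_x, t_y)$, minimizing the
mean squared difference of the *hematoxylin OD* channels over the image
overlap. Initial steps are 0.01 (scale), 0.01 rad, and 2 px; when no
parameter move improves the cost, all steps are halved, until the sweep
improvement falls below `tol` (default 1e-6), `max_iter` sweeps (default
50) are reached, or steps shrink below 1/1000 of their initial size. The
cost is evaluated on the same deterministic bilinear warp used by
`warp_image()`, so the refinement never increases the cost and identical
inputs give identical outputs. An empty overlap at the initial transform is
an error.

`warp_image()` uses bilinear interpolation with background-white fill
(255): bright-field background is white, which is neutral (OD 0)
downstream, so warped-in borders add no spurious stain signal.

# Optical density and stain deconvolution

Bright-field stains attenuate light multiplicatively, so they mix
*additively* in optical density: $OD_c = -\log_{10}(\max(I_c, 1)/I_0)$ per
RGB channel with $I_0 = 255$. The one-intensity-level floor bounds the OD
of saturated pixels at $\log_{10} 255 \approx 2.4065$ and keeps the map
monotone. Deconvolution inverts the 3x3 matrix whose rows are the unit OD
vectors of hematoxylin, the chromogen (AEC or DAB, standard
Ruifrok–Johnston values, overridable), and a residual row completed by the
normalized cross product. Concentrations may be negative off the stain
span; they are retained (preserving exact invertibility, verified to 1e-9
in the tests) and clipped at zero only when measured on cells.

# Cell quantification

Detection is nucleus-driven, mirroring standard digital-pathology
positive-cell detection:

| parameter | default | unit | role |
|---|---|---|---|
| `detection_channel` | hematoxylin_od | — | od_sum alternative for weak counterstain |
| `smoothing_sigma` | 1.5 | µm | Gaussian pre-smoothing |
| `nucleus_threshold` | 0.1 | OD | nucleus segmentation threshold |
| `min/max_nucleus_area` | 10 / 400 | µm² | plausible nucleus sizes |
| `cell_expansion` | 5 | µm | radial cell-compartment growth |

Touching nuclei are split with seeds at the local maxima of the Euclidean
distance transform, enforcing a minimum seed separation of
$2\sqrt{A_{\min}/\pi}$ (twice the radius of the smallest admissible
nucleus; closer maxima are merged by single linkage), and labels grow from
the seeds by distance-constrained propagation inside the binary mask, so
neighbors split along their equidistance line. The cell compartment is a
radial expansion of each nucleus, constrained by neighbors (Voronoi-style
propagation within a disc dilation); cytoplasm = cell minus nucleus. A
cell belongs to the analysis region iff its nucleus centroid is inside the
mask (centroid rule: unambiguous and standard).

The analysis mask is the union of `tumor` polygons minus all `stroma`,
`necrosis` and `artifact` polygons; areas come from exact polygon boolean
algebra (polyclip), not rasterization, so the reported mm² matches the
polygon arithmetic to machine precision. Positivity is a threshold on a
chosen compartment statistic of the chromogen concentration (nucleus
mean/max for nuclear markers such as Foxp3; cell or cytoplasm mean for
surface/cytoplasmic markers such as CD8), and slide-level readouts are
positive cells per mm² of analysis area (density markers) or the
percentage of positive cells over all detected cells (PDL1-style). Zero
detected cells makes the percentage explicitly undefined (`NA`), never 0.

On synthetic tiles, the positivity threshold for the cell-mean chromogen
readout was calibrated once on held-out generator seeds to 0.12 OD: below
that, chromogen from an adjacent positive cell's cytoplasm ring bleeds
into the expanded compartment of its neighbors and inflates the positive
fraction by a few points. Real slides need per-marker thresholds set the
same way any digital-pathology operator would tune them.

# Co-expression across rounds

Detections from different rounds are carried into the reference frame by
the round transform (`transfer_coordinates()`) and paired by
mutual-nearest-neighbor matching with a distance cap (default radius 6 µm,
about one nucleus diameter) — an objective surrogate for the visual
co-localization call usually made on pseudo-fluorescence overlays. Ties
break deterministically by (distance, id); matching is one-to-one and
symmetric in its arguments. Phenotype rules are boolean marker-state
conjunctions evaluated over matched cells. The GZMB:CD8 ratio is computed
at slide level — positive GZMB cells divided by positive CD8 cells, the
form in which such ratios are usually reported — with the stricter
per-cell co-expression counts available from the same summary; a zero
denominator yields an explicit undefined value.

# Cohort statistics

## Exact Wilcoxon signed-rank test

`wilcoxon_signed_rank()` drops zero differences (Wilcoxon's treatment),
mid-ranks the absolute differences, and takes $W = \min(W^+, W^-)$. For
$n \le 25$ the two-sided p-value is exact: mid-ranks are doubled to
integers and the null distribution of the signed-rank sum is accumulated
by a dynamic program equivalent to enumerating all $2^n$ sign assignments,
so ties are handled exactly; $p = \min(1, 2 P(W_{\mathrm{null}} \le W))$
(two-sided as twice the smaller tail under the symmetric null, capped at
1). Beyond $n = 25$ a normal approximation with continuity and tie
correction takes over. All-zero differences are an error ("test
undefined"). The suite checks the exact p against an independent
brute-force enumeration oracle on 200 seeded cases and against
`stats::wilcox.test` on tie-free data, and verifies the empirical type-I
error at $\alpha = 0.05$ over 2,000 null cohorts of $n = 14$.

## Spearman, descriptives, stratification

Spearman's rho is the product-moment correlation of mid-ranks after
pairwise deletion; its default p-value uses the $t$ approximation on
$n - 2$ df (the convention of common statistics packages at these sample
sizes), with the exact permutation bound $2/n!$ reported when
$|\rho| = 1$ and a full-enumeration exact option for $n \le 9$.
Descriptives report mean, SEM ($s/\sqrt{n}$, $n-1$ denominator), median
(mean of central two for even $n$), and range. No multiple-testing
correction is applied anywhere; each reported p-value is marginal, and the
documentation says so rather than hiding it.

Patients are stratified by their *prior* treatments only:
`assign_cohort_group()` tokenizes the prior-treatment string and assigns
`immuno_treated` iff any immune-modulating token (Ipi, Biot, BioCT, IL-2,
IFN) is present, else `naive_ct_rt` (No/CT/RT). Unknown tokens are errors
listing the offender — silent misclassification of a patient would corrupt
every downstream stratified statistic.

## The packaged fixture and its two ambiguities

The packaged table uses comma decimal separators and `"na"` missing codes;
the reader takes an explicit `decimal` argument and never guesses locale
(a dotted numeral under the comma convention is an error naming the
row/column). Two cells of the source table are internally ambiguous, and
the package resolves both explicitly rather than silently:

* **Sampling status.** The table's own on/post-treatment biopsy labels
  disagree with the accompanying narrative (which names patients 2, 6, 10
  as sampled after the last vaccine dose). Only the narrative assignment
  is consistent with the tabulated ratio summaries (post-treatment CD8
  ratio mean 0.5147, on-treatment immuno mean 0.8578; timing average 9.33
  months), so the fixture's `sampling` column follows the narrative while
  `biopsy_timing_printed` preserves the printed labels for inspection.
* **Patient 6 pre-treatment PDL1.** Printed as 0.9748 but only 0 is
  consistent with the printed group means (3.721/4.920). The primary
  fixture carries 0; a second fixture (`table1_cohort("pt6_printed")`)
  carries the printed value. Every signed-rank statistic is identical
  under either reading (the pair's sign and rank do not change).

One count in the source narrative (11 of 14 pairs with a PDL1 increase)
does not match the tabulated values, which contain exactly 10 increases;
`reproduce_table1_stats()` reports the count computed from the data.

# The synthetic generator

`generate_multiround_slide()` emulates the inputs the pipeline consumes:
disk-like hematoxylin-stained nuclei (anti-aliased over a 1 px band —
textureless disks keep the ground truth unambiguous for detection
tolerances) placed without overlap (minimum spacing 2.4 nucleus radii,
rejection sampling with an explicit retry budget) on a pale background
(default level 250); one chromogen round per marker with per-cell labels
drawn from marginal positive fractions and pairwise conditional
co-expression $P(B^+ \mid A^+)$; rendering through the Beer–Lambert
forward model *with the same stain vectors the deconvolution uses*, so a
noiseless, unquantized render deconvolves exactly on cell interiors (a
tested invariant); per-round similarity displacement of the whole frame;
additive Gaussian intensity noise (default sd 2) and 8-bit quantization.
Defaults: 384x384 px at 0.5 µm/px, 120 cells, nucleus radius 3.5 ± 0.4 µm,
hematoxylin 0.7 OD, chromogen 0.9 OD — a mid-power field of a
lymphocyte-dense tumor region. Four noiseless fiducial marks per round
serve as landmarks, so landmark estimation recovers the true round
transforms to 1e-9.

`generate_cohort()` emulates the patient table: log-normal pre values
(default meanlog log 300, sdlog 0.8 — the right order for TIL densities
per mm²), additive paired effect plus Gaussian noise floored at zero,
prior-treatment strings mixed to give roughly the 9:7 naive:immuno split
of the packaged cohort, and independent missingness. A single seeded
generator drives all draws; identical seeds give byte-identical output.

What the generator does *not* emulate — nucleus texture and chromatin
patterns, melanin pigment, tissue folds, stain gradients, out-of-focus
blur, deformable (non-similarity) distortion — bounds what passing tests
show: they validate the algorithms' correctness and calibration on scenes
whose ground truth is exact, not the pipeline's robustness to real-slide
artifacts, which always requires the human parameter tuning and annotation
the tool exposes.

# Numerical choices and problem sizes

* Transform validity, deconvolution round trips, and mask/point geometry
  are asserted at 1e-9; cohort round trips at 1e-12.
* The signed-rank dynamic program doubles mid-ranks to integers (asserted
  to 1e-9 before rounding); counts are doubles, exact for $n \le 25$.
* Fine-alignment cost comparisons are strict (`<`), so plateaus stop the
  descent instead of cycling; candidate scales $\le 0$ are skipped.
* Matching ties break by (distance, id); re-running any pipeline step on
  the same inputs is bit-reproducible.
* Degenerate inputs error early with named messages: empty masks, unknown
  annotation classes, self-intersecting polygons (named per feature),
  unequal landmark counts, all-zero paired differences, zero-variance
  ranks, zero matching denominators.
* Test problem sizes were chosen to exercise every code path at
  interactive cost: 96–512 px tiles, 8–200 cells, 10-seed recovery loops,
  200-case oracle comparisons, and 2,000-replicate null calibration; the
  whole suite runs in well under five minutes on one core.

# Limitations

* Registration is landmark-based plus local refinement; there is no
  automatic (markless) global registration, and no deformable warping.
* Stain vectors are fixed inputs; no automatic stain estimation from the
  image, and at most three stains per round.
* Detection is classical (threshold + distance-transform splitting), not
  learned; heavily overlapping or textured nuclei will under-split.
* The co-expression radius converts visual co-localization into a single
  number; it is a surrogate, and no spatial statistics beyond matching are
  provided.
* Survival analysis and clinical response adjudication are out of scope;
  the lesion-response classifier implements only the diameter-change rule.
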