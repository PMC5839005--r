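---
title: "Methods: CD8+ TIL quantification in brightfield IHC with tilquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CD8+ TIL quantification with tilquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Counting CD8+ tumor-infiltrating lymphocytes (TILs) on chromogenic
immunohistochemistry (IHC) sections, and normalizing the counts to the
annotated tumor area, is a standard readout in immuno-oncology: per-mm²
CD8 densities in the tumor center (TC) and the invasive margin (IM)
characterize the immune contexture of a tumor, and their change under
checkpoint-inhibitor therapy serves as a pharmacodynamic signal.
`tilquant` implements a rule-based image-analysis pipeline for this
readout, the validation framework that compares it cell-by-cell and
field-by-field with pathologist annotations, and the cohort statistics
applied downstream.  Because patient slides cannot ship with a package, a
seeded synthetic slide generator with exact planted ground truth makes
every stage testable in closed loop.

## Image model and stain unmixing

Brightfield IHC obeys Beer-Lambert absorption: per-pixel optical density
`OD_c = -log10(I_c / 255)` in each RGB channel is (to good approximation)
a linear combination of per-stain scalar fields with fixed unit-norm color
vectors.  `unmix_stains()` inverts that mixture by least squares (color
deconvolution), clipping negative loadings.  Two stain profiles are built
in: hematoxylin + DAB for the CD8 mono stain and hematoxylin + purple +
DAB for the CD8/PD-L1 dual stain, where the purple chromogen carries CD8
and DAB carries PD-L1.  The hematoxylin and DAB vectors are the widely
used Ruifrok-Johnston values; the purple vector is the one the synthetic
renderer itself uses.  Analyzing real slides stained with other chromogen
lots requires a measured profile (`stain_profile()` accepts custom
vectors); estimating vectors from the image (Macenko-style) is explicitly
out of scope.

Tissue is separated from glass by a small fixed total-OD floor (default
0.08) followed by morphological closing/opening.  Stain positivity uses an
adaptive threshold: the pointwise maximum of a global OD floor (default
0.15) and `local background mean + 3 SD` computed in a 256 px sliding
window.  The background sample is first separated from stained membranes
by a global Otsu split of the tissue histogram — without that guard,
weakly stained membranes leak into the "background" in densely
infiltrated regions and inflate their own threshold.  The window default
(256 px = 128 µm at 0.5 µm/px) is much larger than a lymphocyte and much
smaller than typical illumination gradients; a two-fold illumination
gradient changes per-half membrane recall by under five points in the
tests.

## Three-stage cell detection

1. **Isolated cells.**  Connected components of the hole-filled positive
   mask whose footprint lies in the configured area range, whose nearest
   neighbouring component centroid is at least one cell diameter away, and
   which contain at most one detected nucleus.
2. **Difficult cells.**  The slide is re-scanned at a relaxed threshold
   (0.6 × adaptive).  Residual components anchored by exactly one nucleus
   become candidates; their footprint is the union of the partial membrane
   signal with the anchoring nucleus, hole-filled — the visible extent of
   a weakly or partially stained cell.  Components without any nucleus are
   dropped, which suppresses chromogen smears and debris.
3. **Cluster resolution.**  Components that are oversized or hold several
   nuclei are split by nucleus-seeded propagation on the Euclidean
   distance transform (a seeded watershed); every fragment containing its
   seed nucleus becomes a candidate.

Nuclei come from thresholding the unmixed hematoxylin field (OD 0.3),
watershed-splitting on the distance transform, and size-filtering
(4–120 µm²).

Candidates pass the acceptance filter iff the footprint area is within
20–250 µm², compactness clears a permissive floor (0.15), and the cell
either has an associated nucleus or is strongly stained (mean CD8 OD at
least 1.5 × the local threshold) with membrane completeness of at least
0.33.  Weakly stained or partial candidates without a nucleus are always
discarded; the qualitative rule in the source description is
"generally discarded", which we harden into an unconditional rule for
determinism.  Every rejection is logged with the rule that fired.  The
original system's numeric thresholds live in undisclosed commercial rule
sets, so all values here are surrogates chosen from lymphocyte biology
(diameters of roughly 5–15 µm, with the area ceiling at 250 µm² leaving
headroom for stretched elongate cells); all are `detection_config()`
parameters and validated only against synthetic truth, not against the
original study's slides.

## Morphometry and elongate TILs

Per-cell features: area, oriented bounding box (OBB), ellipticity
(minor/major axis ratio of the moment-equivalent ellipse), compactness
(4πA/P² with the 8-connected contour length), and membrane completeness
(fraction of equal-angle boundary bins whose mean CD8 OD is positive; 16
bins).  The OBB axes are the eigenvectors of the population covariance of
pixel-center coordinates; extents add one pixel so that a one-pixel line
has nonzero width — whether the original box includes partial pixels is
unstated, so this convention is documented rather than inferred.

A CD8+ cell is **elongate** when it is isolated from other CD8+ cells,
its OBB width is strictly below 10 µm, and its length-to-width ratio is
strictly above 2.3.  The criteria source states isolation without a
number; we quantify it as nearest-neighbour boundary distance (centroid
distance minus both equivalent radii) above one mean cell diameter
(10 µm), configurable in `elongate_criteria()`.  Elongate shape is a
candidate morphological correlate of lymphocyte motility; the package
makes no claim beyond the geometry.

## Regions: tumor center and invasive margin

The IM is modeled as the band extending 250 µm beyond and 250 µm inside
the annotated tumor boundary; TC is the remaining interior.  Because the
original band is drawn free-hand ("approximately 250 µm"), a
deterministic surrogate is required: `build_regions()` buffers the
rasterized tumor annotation with the Euclidean distance transform (round
joins).  Only the outer tumor contour is buffered; whether internal
tumor–stroma interfaces should also carry a band is not specified in the
source, so the outer-contour choice is the documented default.  Three
modes cover the annotation styles: `resection_im_tc` (IM band + interior
TC), `clinical_tumor_only` (single "tumor" annotation extended 250 µm
outward, no IM — the biopsy situation) and `no_im` (e.g. lymphoma, where
an IM is not meaningful).  Exclusion polygons (necrosis, artifacts) are
subtracted from every region before areas or counts are computed; they
come from the annotation input and are never auto-detected.

Geometry is evaluated on rasters: pixel centers at integer (x, y),
membership by the even-odd rule with boundary pixels inside, areas as
pixel counts × (µm/px / 1000)².  A 2×2 mm square tumor with 250 µm bands
reproduces the analytic buffered areas (TC 2.25 mm²; IM ≈ 3.946 mm²)
within a fraction of a percent at 2 µm/px.  Cells are assigned to regions
by centroid with priority excluded > IM > TC > outside; a centroid at the
erosion radius itself falls in the IM (strict inequality), which is the
deterministic tie-break.

## Dual stain

In dual mode the CD8 pipeline runs unchanged on the purple channel.
PD-L1 positivity is pixel-wise on the DAB channel — an area
classification, not per-tumor-cell scoring, since only area-based display
is described for the original assay.  Positive pixels are binned into
three ordered intensity grades; the OD cut points (0.2 / 0.45 / 0.7) are
configurable surrogates because no bin definitions are published.
`count_cd8_by_pdl1()` partitions tumor into PD-L1+/− sub-areas with exact
count conservation, and `mono_dual_comparability()` applies the
concordance statistics to paired per-sample counts from both stains.

## Validation framework

Fields of view (250 or 500 µm diameter, at least 13 over at least nine
slides in the reference design) are placed by seeded round-robin over
slides, non-overlapping, spread over low/medium/high local-density
terciles when cell positions are available.  Within each field, detected
and annotated cells are matched one-to-one by minimum-cost bipartite
assignment gated at 7.5 µm (about one lymphocyte radius plus localization
error; the source states no radius).  The solver is a Hungarian algorithm
applied per connected component of the gated graph, with an
unmatched-penalty construction that guarantees minimum cost at maximum
cardinality; tests verify it against exhaustive permutation search.
TP/FP/FN are pooled over fields before F1 — pooling, not averaging, is
the stated rule.

Agreement of per-field counts uses Lin's concordance correlation
coefficient (population moments), Pearson, and Spearman (mid-ranks).  The
one-sided 95% lower bound of the CCC comes from a nonparametric
percentile bootstrap with 10,000 iterations by default; the resampling
unit is the field, the unit of the reference scatter plots (whether the
original bootstrap resampled fields or cells is not stated).  The bound
is categorized by the McBride cut points: ≥0.9 almost perfect, ≥0.8
substantial, ≥0.65 moderate, else poor.  With several annotators the
consolidated score is the per-field median of the annotator counts —
robust, and again a documented choice where no formula is given.  A
plausibility check screens result tables for negative or non-integer
counts, negative areas/densities, count/area/density inconsistency
(relative 10⁻⁶), missing values and duplicate keys.

## Cohort statistics

`compute_densities()` emits one record per region plus the `tumor_area`
aggregate (counts and areas additive); zero-area regions report a missing
density, never zero.  TC-vs-IM uses the two-sided Wilcoxon signed-rank
test: zero differences dropped (Wilcoxon's rule), mid-ranks for ties,
exact p for n ≤ 25 via generating-function convolution over doubled
mid-ranks (the standard shift algorithm cannot handle ties; enumeration
is the test-side oracle), tie-corrected normal approximation above.  The
original report of "Wilcoxon T, using T < 0.05" appears to conflate the
statistic with the p-value; the package returns both `statistic` (T+, the
positive-rank sum) and `p_value` explicitly.  Pre/post-treatment
densities use the two-sided paired t test with its 95% CI, delegated to
`stats::t.test`; a zero-variance difference vector degenerates to p = 1
at zero mean (documented convention).  Two-sided tests are used
throughout — stated for the paired design, assumed for TC-vs-IM symmetry.

## The synthetic generator

`generate_slide()` renders, in OD space: a faint hematoxylin tissue wash
(0.09 OD) on a rectangular tissue region; round cells as membrane annuli
(ring OD ≈ 0.6–1.0, thickness ≈ 1.3 µm) with interior nuclei (0.55 OD,
0.55 × cell size); elongate cells as rotated elliptical annuli whose
width (4.5–8 µm) and axis ratio (2.6–3.8) satisfy the elongate criteria
with at least 10% margin so that pixelization cannot flip them;
optionally partial membrane arcs (40–70% coverage), a necrotic blob
recorded as exclusion, and graded PD-L1 blobs in dual mode.  Placement is
a hard-core process (isolated cells ≥ 1.3 diameters apart; elongate cells
given wide clearance) with Matérn-style clusters whose members sit ≈ 0.7
diameters apart — rings merge, nuclei stay distinct — to exercise all
three detection stages.  Fields are mixed through the stain vectors, then
multiplied by a low-frequency illumination field (±5%), perturbed with
Gaussian sensor noise (SD 2 of 255), and quantized to 8 bits.  Identical
seeds give bit-identical rasters and truth.

Because mixing is linear in OD, deconvolution is exactly invertible in
the noise-free limit — the generator doubles as an analytic oracle for
the unmixing, threshold, detection and morphometry modules.  What it does
**not** emulate: real stain variability between labs and runs, scanner
point-spread and compression artifacts, stromal texture and
non-lymphocyte DAB-positive objects, lymphocytolysis and nuclear debris,
and genuinely ambiguous packed foci where neither pathologist nor
algorithm can count single cells.  Passing the closed-loop tests
therefore demonstrates internal correctness of the implemented rules, not
clinical performance on patient slides.

Generator defaults are the package's study conditions: density via a
Poisson draw at the configured target, 5% elongate, 20% clustered, 5%
partial-ring cells, 9 µm mean diameter.  The nine cohort presets
(`indication_presets()`) are synthetic settings spanning a realistic
dynamic range, with lymphoma richest (median 1500/mm²) and
prostate/kidney poorest (≈ 120–150/mm²); they mirror only the qualitative
ordering of the published landscape, since the per-sample values are not
deposited.  Paired biopsies draw screening densities lognormal (median
400/mm², sdlog 0.5) and add the configured on-treatment shift plus
Gaussian noise (SD 300/mm², clamped at zero) — a within-patient
variability a trial of this kind would consider realistic.  The 365/mm²
shift used in tests and the acceptance script is the published effect
size employed as a simulation setting.

## Numerical choices and problem sizes

All RNG flows through per-call seeds with save/restore of the global
state; derived seeds stay inside the 32-bit range.  Detection is fully
deterministic given the raster.  The test suite runs its closed-loop
checks on ≈ 1 mm² slides at 0.5 µm/px (2024² px) for densities 500–2000
cells/mm², the region oracle at 2 µm/px, the bootstrap coverage check at
1,000 meta-replicates × 2,000 iterations, and the mono/dual comparability
on 24 paired 512² renders — sizes chosen so the whole suite completes on
a single CPU in minutes while leaving the statistical tolerances
meaningful.

## Known limitations

* Stain profiles are fixed inputs; no automatic vector estimation.
* Whole-slide pyramidal formats are out of scope (flat rasters only), as
  is serial-section co-registration of annotations.
* No CD8− cell detection and no machine-learned classifiers — the
  pipeline is deliberately rule-based and deterministic.
* The isolation component of the elongate criterion and every filter
  threshold are surrogates; on real material they would be tuned against
  pathologist truth before use.
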