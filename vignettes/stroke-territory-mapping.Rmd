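---
title: "Flattening diffusion MRI into territory maps: methods and design"
author: "strokemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flattening diffusion MRI into territory maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokemap)
```

## The problem

Acute ischemic stroke appears hyperintense on diffusion-weighted MRI (DWI).
Reading a DWI study means scrolling through a stack of axial slices; a
single static image of the whole brain would be easier to print, archive,
and overlay with surface modalities such as EEG. `strokemap` implements a
dimensionality reduction that projects every brain voxel radially onto a
sphere around the brain and flattens that sphere to a two-dimensional map,
then asks whether the flattened representation is still diagnostically
useful: can the affected brain-artery territory (ACA, superior/inferior
MCA, PCA, PICA) be recognised from the 2D map alone?

The package contains the full chain — intensity segmentation, projection,
healthy reference, territory atlas, two-criterion classifier,
cross-validated diagnostic accuracy — plus a synthetic phantom generator so
every stage is testable end to end without patient data.

## Intensity segmentation

All thresholds come from the volume's own intensity histogram (default bin
width 1 a.u. for data in the 0–400 a.u. regime; counts are smoothed with a
5-bin moving average before any extremum detection, because raw counts are
too noisy for reliable peaks). Three landmarks are located:

* **Background/brain cut-off** — the minimum of the dip between the two
  dominant histogram peaks (the tall low-intensity background peak and the
  broad healthy-brain peak). A second "peak" must reach at least 5% of the
  main peak's height to count as a mode; otherwise the histogram is
  declared unimodal and the separation fails loudly rather than silently.
  When the dip is a flat run of tied minima — the usual case on clean
  phantoms whose populations do not overlap — the *central* tied bin is
  taken. Taking the lowest tied bin instead would drag the reflected stroke
  cut-off (below) upward by half the dip width and clip a substantial part
  of genuine lesion signal; unique minima are unaffected by this choice.
* **Brain mode** — the highest smoothed count above the background cut-off.
* **Brain/stroke cut-off** — the healthy-brain distribution is symmetric,
  while sparse hyperintense stroke values skew the observed peak to the
  right. The cut-off is therefore the dip minimum *reflected across the
  brain mode*: `2 * brainMode - backgroundCutoff`. In this implementation
  the dip-minimum intensity and the background cut-off are the same number
  by construction, so the two conceivable readings of "the minimum value
  from the left side" coincide and no switch between them is needed.

A one-sample Kolmogorov–Smirnov test against a Gaussian with the sample's
own moments (`gaussianityCheck`) quantifies how reasonable the symmetry
assumption is at the data's signal-to-noise level. MRI magnitude noise is
Rician, but at the emulated SNR the Gaussian approximation holds; the check
is advisory and never blocks the pipeline. Because the moments are
estimated from the data the test is conservative (empirical rejection rate
below the nominal 5% on Gaussian samples).

## Projection and flattening

Brain voxels are projected *radially* from a configurable centre (on
patients, the ventral lower mesencephalon between the cerebral peduncles —
central and anatomically distinct; on phantoms, the brain centroid). All
voxels on one ray share one spherical direction `(λ, θ)`; the sphere radius
defaults to the largest centre-to-voxel distance, i.e. a sphere around the
brain surface. Flattening uses the closed-form map

x = 8·r·λ·cos θ / π,  y = 2·r·sin θ,

applied exactly as stated. Note this variant spans an 8r-wide, 4r-tall
footprint (4:1 aspect) and is *not* the canonical equal-area Mollweide
projection (2:1, transcendental auxiliary angle); the canonical variant is
available behind `canonical = TRUE` for comparison but is not the default.
The polar axis is anatomical superior, longitude zero is anterior, and the
left hemisphere lands on the left half of the map.

Each projected voxel is rasterised to the nearest pixel; where several
voxels share a pixel the **maximum** intensity wins, so hyperintense stroke
signal is never hidden behind healthy tissue, and the per-pixel contributor
count is recorded. The default raster is 960 × 240 pixels. The 4:1 aspect
follows from the formulas; the resolution was fixed once so that the pixel
grid matches the data density of the default phantom — about 40% of
occupied pixels then collect more than one voxel (maximum multiplicities
around 20), the regime the max-aggregation rule is designed for. A coarser
720 × 180 raster pushes the multi-contributor fraction to ~0.7 and wastes
the resolution of the data; a much finer one leaves most pixels empty.

## Healthy reference and flagging

A per-pixel healthy reference (`buildDiffusionReference`) stores the mean
and standard deviation of healthy diffusion levels over a set of maps —
population divisor *n* throughout, the convention that reproduces the
published aggregate rows. On phantoms the healthy maps are obtained by
`mirrorHealthyHemisphere`: lesions are always planted in the left
hemisphere, so replacing the left half by the mirrored right half yields an
all-healthy map (the mirroring mechanics on real data are not prescribed;
contralateral mirroring is this package's choice).

A patient pixel is **stroke-indicating** when its value exceeds the
reference mean by more than `k` standard deviations at that pixel.
Flagging is one-sided (DWI stroke is hyperintense; a two-sided mode exists
behind `twoSided = TRUE`), and pixels never covered by a reference map are
never flagged and are excluded from all area denominators.

The sigma level defaults to `k = 2` and can be selected with
`chooseSigmaLevel`, which minimises the mean discrepancy between the 3D
stroke-per-brain volume ratio and the 2D flagged-area fraction (the
SPB comparison; relative discrepancy by default, absolute percentage
points behind a flag, the published magnitudes suggesting the relative
reading). Ties break toward the smaller k.

## Territory atlas and classifier

The atlas merges the stroke masks of cases with a single-territory
diagnosis and widespread lesions (`buildTerritoryAtlas`); provenance is
recorded so atlas cases can be excluded from evaluation, preventing biased
accuracy estimates. A territory is called **positive** when either

1. its *coverage* — flagged pixels inside the territory mask divided by the
   mask area — exceeds the territory's area cut-off, or
2. its *bulk* — flagged pixels inside the territory divided by all flagged
   pixels — exceeds the territory's bulk cut-off.

Comparisons are strict (`>`), and a bulk cut-off of exactly 0 *disables*
criterion 2 for that territory: under either `>` or `>=` a literal 0%
threshold degenerates (firing on any single scattered pixel, or on every
territory), which would contradict the reported specificity; the published
zeros for ACA/supMCA/infMCA are therefore read as "criterion 2 unused".
With no flagged pixels at all, every territory is negative and all bulk
values are defined as 0.

Cut-offs are optimised per territory by grid search (0–100% in 5% steps —
all published cut-offs are multiples of 5) maximising the Youden index
`Y = sensitivity + specificity − 1` of the pooled patient-by-territory
decisions; pooling over patients (rather than averaging per-patient
indices) keeps degenerate folds well-defined. Whether the original
optimisation was pooled or per-territory-joint is not stated; per-territory
optimisation matches the published per-territory cut-offs and is adopted.
Ties break toward the largest area cut-off, then the largest bulk cut-off —
the most conservative rule among equals.

## Validation statistics

`diagnosticStats` implements the standard definitions: sensitivity
TP/(TP+FN), specificity TN/(TN+FP), PPV, NPV, PLR = sens/(1−spec),
NLR = (1−sens)/spec. (The source report's formula block contains printed
typos — TP/(TP+TN) and TN/(TN+FN) — which its own result table contradicts;
the standard definitions reproduce every published row from the published
counts.) At perfect specificity the PLR is undefined and reported as `NA`;
a compatibility mode reports 0 instead, matching the published table, and
is the default inside the validation loop so fold means remain defined.

`crossValidate` shuffles the cohort with a recorded seed, splits it into
contiguous near-equal folds (91 cases and 10 folds give nine folds of 9 and
one of 10), optimises cut-offs on nine folds and evaluates on the held-out
fold, and averages fold statistics with population-SD aggregation. An
identifier audit refuses any fold whose held-out cases appear in its
training set. `independentValidate` optimises on the full training cohort
and evaluates pooled counts on a disjoint hold-out set, refusing
overlapping identifiers.

## The phantom generator

`makeBrainPhantom` builds what the pipeline assumes and nothing more: an
axis-aligned ellipsoidal brain (default semi-axes 70 × 85 × 60 mm) on a
96³ grid at 2 mm isotropic spacing, Gaussian additive noise (SD 10 a.u.;
a Rician magnitude option exists but the Gaussian assumption is exactly
what the segmentation relies on at this SNR), and intensity levels mimicking
the clinical histogram structure: background ≈ 20 a.u., healthy brain
≈ 180 a.u., stroke ≈ 300 a.u. Intensities are clipped at zero.

Lesions are single compact blobs: the requested fraction of brain volume
nearest to a random seed point inside the target territory's wedge,
restricted to the left hemisphere (strokes are unilateral and the mirroring
step needs a known healthy side). Territory wedges are fixed angular
sectors in the projection's own spherical coordinates (`territoryWedges()`
prints the constants): ACA anterior–superior at the midline, the MCA
divisions lateral (superior and inferior bands), PCA posterior, PICA
inferior–posterior. They are pairwise disjoint, bilateral, and jointly
cover over 80% of the brain surface; because they are defined relative to
the projection centre, a planted lesion's map footprint is guaranteed to
fall inside its territory's footprint — which is what makes the phantoms a
*clean* test of the machinery rather than a model of anatomy.

Cohort lesion burdens are drawn log-normally around the clinical median of
2.3% of brain volume, clipped to [0.8%, 4%] — the upper clip keeps every
territory wedge able to accommodate its lesion (the smallest, ACA-left,
holds about 4.5% of brain volume). Atlas cases instead get "widespread"
lesions filling 70% of their wedge's capacity, mirroring the preference for
widespread single-territory lesions when building the reference atlas.

Two optional realism features exist for designed experiments and are *off*
by default: `gradientAmplitude` adds a smooth linear intensity gradient in
a random direction (bias field / regional diffusion differences), and
`lesionProfile = "graded"` gives lesions a bright core decaying to a 30%
contrast rim. What the phantoms deliberately omit: anatomical brain shape,
partial-volume effects, multi-lesion and watershed infarcts, registration
error between subjects. Passing tests on phantoms therefore demonstrates
the correctness of the machinery, not clinical performance.

## The sigma-level experiment

On clean default phantoms the threshold-derived 3D stroke-per-brain ratio
and the k = 3 flagged area agree almost by construction — the reflected 3D
cut-off sits about 2.5 SD above the brain level, which is also where the
k = 3 flagging threshold sits — so a selection experiment run that way
always prefers k = 3 and says nothing about the trade-off the sigma level
actually controls. The designed cohort used in the tests and the acceptance
script therefore combines: graded-rim lesions of moderate contrast
(+45 a.u.), a ±25 a.u. bias field (which inflates the per-pixel reference
SD without shifting whole cases), and the *ground-truth* 3D burden as the
comparison target (available on phantoms, and the quantity the
threshold-based ratio estimates). Under those conditions 1 SD over-flags
healthy tissue (mean discrepancy ≈ 320%), 3 SD clips the lesion rim
(≈ 60%), and 2 SD wins (≈ 25%) — reproducing the qualitative U-shape that
motivates the 2-SD default.

## Numerical choices and degenerate inputs

* Histogram bin edges are aligned to multiples of the bin width; scaling
  intensities and the bin width together scales all cut-offs (checked to
  within one bin).
* A voxel exactly at the projection centre has no direction;
  `toSpherical` refuses it, and `projectVolume` maps such a voxel to the
  map origin (documented, deterministic). At the poles longitude is
  canonicalised to 0.
* Sphere radius cancels in rasterisation, so it only fixes the physical
  scale of map coordinates.
* Zero-variance samples, empty masks, empty margins, unreadable files, and
  unknown territory names all fail with explicit errors rather than
  propagating NaNs.
* Every stochastic step takes an explicit seed, and cohort generation,
  fold assignment and the full study are pure functions of their
  configuration.

## Problem sizes

The test suite and the acceptance script run the full pipeline on a
60-case evaluation cohort plus 14 atlas cases at 96³ voxels per phantom
(about half a minute on one core), and use 48³ or 36³ grids with the same
brain dimensions in millimetres for unit-level checks. These sizes were
chosen as the smallest at which every histogram, projection and
classification property is comfortably away from discretisation artefacts.

## Known limitations

* The printed flattening formulas are not area-preserving; quantitative
  area comparisons across latitudes inherit that distortion (the canonical
  variant exists for comparison).
* Deep lesions project onto the same pixels as the tissue above them; only
  the maximum survives, so depth information is lost by design. A
  multi-shell ("onion") projection would address this and is out of scope.
* The healthy reference assumes all maps share one raster geometry; there
  is no inter-subject registration beyond the common map frame.
* Laterality (left vs right) is not part of the territory call.
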