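---
title: "Region-resolved immune scoring from nuclei maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-resolved immune scoring from nuclei maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunofront)
```

## The analysis in one paragraph

Deep-learning models applied to H&E-stained colorectal-cancer whole-slide
images produce two artifacts this package consumes: a table of nucleus
centroids with a cell class for each (epithelial, lymphocyte, neutrophil,
plasma cell, eosinophil, mitosis, connective), and a tissue-type label
raster with nine classes at a known resolution in micrometres per pixel.
From these, `immunofront` derives region-resolved immune scores — how many
lymphocytes and eosinophils accompany each tumor cell at the invasive front
versus the tumor center, and how often lymphocytes sit *between* tumor
epithelial cells (intraepithelial lymphocytes, IELs) — and evaluates their
prognostic value against time to recurrence with Cox proportional-hazards
models. Everything downstream of the neural networks is implemented here;
the networks themselves are out of scope, and a synthetic-data generator
with known ground truth stands in for patient material.

## Coordinate conventions

All cell positions are micrometres in slide space, origin top-left, x to
the right, y downward. Raster pixel (r, c) covers the half-open square
[(c−1)·mpp, c·mpp) × [(r−1)·mpp, r·mpp). Every module shares this
convention; GeoJSON exports use the same axes.

## From nucleus classes to semantic classes

Neutrophils, plasma cells, mitoses and connective-tissue cells are grouped
as "other". Epithelial nuclei are split into tumor versus normal epithelium
using the tissue raster: the majority tissue class within a 25 µm disk
around the centroid decides (ties go to the class of the nearest labelled
pixel). The 25 µm disk matches the nucleus-scale neighbourhood used for the
intraepithelial region, so one length scale governs all nucleus-level
context. How nucleus-level calls should meet tissue-level labels is a
genuinely open design point; a majority vote is robust against single
mislabelled pixels at class boundaries, which is the failure mode that
matters at 40x-derived label rasters.

Before any context query the tissue map is *merged*: lymphoid-aggregate
pixels are recoded as stroma, and muscle and stroma share one working code.
Aggregates are thereby never tumor, muscle/adipose or normal-mucosa context
— cell-level radius clustering (below) is the single authority on
aggregate exclusion, which keeps the exclusion rule identical for tissue
types and for detections. The raw muscle and adipose labels remain
available to the front estimator, which depends on the tumor/muscle
topology and would be meaningless after a literal muscle–stroma merge.

## Estimating the invasive front

Colorectal carcinomas grow into the muscularis and adipose tissue. The
invasive front line is therefore estimated as the set of points equidistant
between the tumor-epithelium mask and the union of the muscle and adipose
masks: with Euclidean distance transforms $d_{tum}$ and $d_{inv}$ computed
on the raster, the front is the zero contour of $d_{tum} - d_{inv}$,
vectorised to polylines (`grDevices::contourLines`) and simplified with a
one-pixel Douglas–Peucker tolerance. Two filters apply per vertex:

* vertices where $d_{tum} + d_{inv} > 1000$ µm are dropped — there is no
  tumor/muscle interface within the band's diameter there;
* vertices whose nearest normal-epithelium pixel is closer than their
  nearest muscle/adipose pixel are dropped, so no front is drawn along the
  normal mucosa.

Fragments shorter than 500 µm (configurable, `min_front_length_um`) are
discarded as spurious one-pixel ridges. A slide may legitimately have no
front — no tumor, no muscle/adipose, or nothing surviving the filters —
and this is reported as `detected = FALSE`, never an error; such slides are
excluded from region-specific scores but keep their whole-slide scores.

Tumor cells within 500 µm (ties inclusive) of the line are *front*, the
rest are *center*. The band applies to tumor cells only; immune cells are
attributed to a region through their nearest tumor cell (see Scoring), so
stroma-side immune cells near the front count toward the front without
needing their own band test.

## Lymphoid structures and the intraepithelial region

Lymphocytes are clustered by linking pairs at ≤ 20 µm and taking connected
components. Components of more than 500 cells are lymphoid aggregates, of
more than 50 000 cells lymph nodes; both thresholds are strictly exclusive
(a 500-cell component is neither). Members are excluded from all scoring so
organised lymphoid tissue does not masquerade as stromal infiltrate.
Additionally, cells of *every* class inside the convex hull of a lymph-node
component are excluded: a lymph node caught on the slide is not tumor
microenvironment, and its resident eosinophils and epithelium would
otherwise leak into the scores. The thresholds themselves are treated as
fixed constants of the method.

The intraepithelial region is the union of 25 µm disks around tumor
epithelial centroids minus the union of 12.5 µm disks around
connective-class centroids. Membership tests are exact nearest-distance
tests. The region's area is computed by scanline integration: on each
scanline the x-coverage of a disk union is an exact union of intervals and
the subtraction is exact interval arithmetic, so the only approximation is
the y-step (default 0.05 µm; the relative error on a single 25 µm disk is
below 10⁻⁴). This was chosen over polygonal buffers because interval
arithmetic has no vertex-count/accuracy trade-off and needs no polygon
clipping machinery.

A non-excluded lymphocyte inside the region is an IEL. The IEL score is the
ratio of tumor cells with at least one IEL within 25 µm (the
`adjacency_radius_um`, reusing the dilation radius — "adjacent" needs a
definition and a second length scale was not warranted) to tumor cells with
none. This per-tumor-cell formulation is robust to crypt misclassification,
which inflates raw IEL counts.

## Scoring

Immune cells are counted in 10 µm distance bins up to 500 µm for the
descriptive profiles, and in a fixed 200 µm radius for the survival scores
— wide enough to capture direct tumor–immune interaction, narrow enough to
exclude disease-unrelated cells. Counting is *unique*: each immune cell is
binned once, by the distance to its nearest tumor cell, and attributed to
the region (front/center) of that nearest tumor cell. This construction
makes double counting impossible by design and yields an exact conservation
law — front score × front tumor cells + center score × center tumor cells
equals the number of unique immune cells within 200 µm of any tumor cell —
which the test suite verifies against brute force on random instances. Ties
at exactly 200 µm count as inside, consistent with the 500 µm band rule.
Profiles normalise per whole-slide tumor cell (they are slide-level
descriptive output); region scores normalise by the region's tumor-cell
count.

The six region scores are LymF/LymC/LymA and EosF/EosC/EosA (front, center,
anywhere). Patients with several slides get tumor-cell-weighted averages:
region scores weighted by the slide's regional tumor count, whole-slide
scores and the IEL ratio by total tumor count, slides missing a score
dropped from that score's average only.

## Normalization

Cohorts differ systematically (staining, scanners, case mix), so scores are
min-max scaled per cohort using the 5th and 95th percentiles (linear
interpolation between order statistics, `quantile` type 7) of *stage II*
patients as anchors. Values are deliberately not clipped: outliers — which
typically arise in cases with few tumor cells — keep values above 1.0 and
stay in the analysis. Degenerate anchors (p95 = p5) raise an error rather
than silently producing infinities.

## Survival analysis

The endpoint is time to recurrence, censored administratively at 60 months:
events after the cutoff are recoded as censored at 60. Lymphocyte and
eosinophil scores enter models as log(1 + max(x, 0)) — `log1p` rather than
a raw log because normalized scores can be exactly zero, with a floor
because values slightly below the stage-II 5th percentile map below zero.
The IEL ratio is left untransformed.

Cox models use the Efron tie approximation (stated explicitly because it
changes third-decimal coefficients against Breslow), drop incomplete rows
per model with the count recorded, warn below 10 events, and report hazard
ratios with 95% confidence intervals, Wald p-values, the model
log-likelihood, AIC = 2k − 2 logLik, and a proportional-hazards diagnostic
(scaled Schoenfeld residuals). Models are compared by AIC only when fitted
on the identical patient subset; anything else raises an error. A
coefficient diverging past |β| > 15 is reported as separation. Kaplan–Meier
quartile plots compute their quartile cuts on the full cohort before any
subsetting, so subgroup panels share one quartile definition; per-quartile
p-values are Wald tests against the lowest quartile from a single
univariate Cox fit on the quartile indicators. No multiple-testing
correction is applied anywhere: conclusions are drawn from individual
comparisons, not a global hypothesis.

## The synthetic-data generators

`simulate_slide()` draws a layered geometry that mirrors the natural
topology the front estimator exploits: a normal-mucosa band at the top, a
tumor band (or blob), a muscle band at the bottom separated from the tumor
by a stroma gap whose analytic midline is the true front. Tumor cells are a
homogeneous Poisson process at 1500 cells/mm² inside tumor epithelium —
a typical epithelial nuclear density for colorectal resections. Immune
cells are inhomogeneous Poisson processes realised by thinning: candidates
at a base intensity (600/mm² lymphocytes, 60/mm² eosinophils) are kept with
probability exp(−d/λ) of the distance d to the nearest tumor cell
(λ = 100 µm and 80 µm), reproducing the peaked-near-tumor, decaying
distance profiles seen on real slides and an eosinophil burden of roughly
4–6 per 100 tumor cells within 200 µm. Planted aggregates are isotropic
Gaussian clusters truncated at 1.5 standard deviations — truncation keeps
the edge density high enough that nearest-neighbour spacing stays below the
20 µm linkage radius, so a planted structure is guaranteed to surface as
one connected component. IELs are planted by giving a configurable fraction
of tumor cells a lymphocyte at 2–12 µm. The generator returns ground truth
computed *by construction*: the true front line, each tumor cell's true
region, planted memberships, and the expected unique immune count within
200 µm obtained by quadrature of the thinned intensity.

What the generator does not emulate: glandular microarchitecture (so
ambient lymphocytes near tumor cells become IELs far more often than in
real epithelium — the default slide's IEL ratio of ~3.5 reflects this, and
IEL-recovery tests therefore use dedicated low-ambient specs), classifier
noise, staining artefacts, serrated or mucinous growth patterns, and
fragmented TCGA-style partial resections. Passing tests demonstrate
algorithmic correctness on known geometry, not clinical performance.

`simulate_cohort()` draws clinicopathological covariates from realistic
marginals (stage II prevalence 0.42, MSI 0.19, matching a four-cohort
colorectal collective of ~1100 analysable patients with ~230 events),
correlated normalized scores through an explicit latent-factor Gaussian
copula over log-normal margins — the front scores of lymphocytes and
eosinophils carry a Spearman correlation of 0.64, front and center scores
of one cell type 0.63, the IEL score independent — and recurrence times by
inverse-transform sampling under a proportional-hazards model with an
exponential baseline. The baseline rate is calibrated per replicate by
root-finding so the *expected* number of observed events matches the
target; censoring is administrative, uniform on 24–84 months before the
60-month cutoff. True hazard ratios are supplied per unit of the analysis
covariate (i.e. on the log1p scale for lymphocyte/eosinophil scores), so
parameter-recovery tests compare like with like.

## Numerical choices and degenerate inputs

* Percentiles and quartiles: linear interpolation (type 7) throughout,
  stated for bit-reproducibility.
* Distance ties: ≤ at both 200 µm and 500 µm.
* Front vertices sample the distance fields at the nearest pixel; the
  acceptance tests demonstrate sub-pixel midline accuracy on half-plane and
  annulus layouts regardless.
* Zero tumor cells: profiles warn and return empty; scores return `NA`;
  the IEL ratio returns `NA` with a warning (and 0 when tumor cells exist
  but no IEL does).
* All-background rasters, absent fronts, empty immune groups and empty
  components are valid inputs with defined outputs, not errors.
* Determinism: the pipeline itself is free of randomness; the generators
  consume one explicit seed and reruns produce byte-identical CSVs.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations were sized as the smallest
instances that still exercise every code path at the study's parameter
scale: slides of 4 × 4 mm (about 20 000 nuclei) for pipeline runs, one
4 × 12 mm slide for the 600/60 000 planted-structure check, cohorts of
n = 1122 with 229 expected events for hazard-ratio recovery (200
replicates in the tests), and n = 300 with 70 events for null calibration
(2000 replicates). These choices are the package's own; larger instances
change nothing qualitatively.

## Known limitations

* The front estimator inherits the raster resolution; very fine mpp values
  increase distance-transform cost quadratically.
* The spec of "adjacent" for the IEL ratio (25 µm) and the majority-vote
  context rule are method choices where the underlying approach is
  published only as prose; both are recorded in `pipeline_config()` so they
  are auditable and changeable.
* Whether eosinophils inside lymphoid aggregates should be excluded is not
  settled; this implementation excludes all cells inside lymph-node hulls
  but only lymphocytes of aggregates, the most conservative reading that
  still protects lymphocyte counts.
* Real multi-slide patients violate the generator's one-slide-per-patient
  default; `aggregate_patients()` is tested with synthetic multi-slide
  tables instead.
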