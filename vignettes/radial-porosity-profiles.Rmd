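---
title: "Radial porosity profiles: measurement model and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial porosity profiles: measurement model and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rppbone)
```

## The measurement model

A radial porosity profile (RPP) summarises how vascularised a limb-bone
cortex is along its radial growth direction. Because cortical bone is
deposited outward, the inner cortex preserves the oldest posthatching
growth record and the periosteal surface the youngest; primary vascular
porosity decreases as deposition slows, so the radial porosity gradient is
a frozen record of the element's growth trajectory. Fast-growing
(altricial) elements keep a porous cortex far out; slow-growing
(precocial) elements compact early. Measuring porosity in radial bins
therefore turns one histological section into a four-point developmental
trajectory that can be clustered and modelled across elements, individuals
and taxa — including fossils, where no longitudinal observation is
possible.

The measurement protocol implemented here:

1. **Sectors.** Up to `S = 3` polygonal measurement sectors per section,
   each bounded by two borders following the inner and outer
   posthatching-cortex surfaces and two roughly radial sides
   (`sector_spec()`, or `place_sectors_auto()` on well-segmented images).
2. **Quadrants.** Each radial side is split at arc-length fractions 1/4,
   2/4, 3/4 and corresponding split points are joined by separators that
   follow the section circumference, giving quadrants `a` (innermost,
   oldest) to `d` (outermost, youngest) (`build_quadrants()`).
3. **Porosity.** In each quadrant, porosity is the summed area of primary
   vascular spaces as a percentage of quadrant area, after subtracting
   areas with no primary record: secondary remodelling (including
   compacted coarse cancellous bone), the outer circumferential layer
   (OCL) and the endosteal lamellar layer (EL) (`quadrant_porosity()`).
   Secondarily enlarged primary canals without secondary deposition count
   as vascular space; that distinction is the annotator's, encoded in the
   class raster.
4. **Missing rules.** A quadrant whose excluded-plus-non-cortex fraction
   exceeds a threshold (default 0.5, configurable) is reported missing —
   its primary record is mostly obliterated. A trajectory is analysable
   when at least two of its four sector-averaged points exist; k-means and
   GBTM additionally require complete profiles, while the distance-based
   methods tolerate up to two missing points.
5. **Mean RPP.** Quadrant-wise averaging over sectors uses available-case
   divisors (the count of sectors where that quadrant was measurable), the
   minimal consistent extension of complete-sector averaging to the
   incomplete profiles real material produces.

Centred RPPs (`center_rpp()`) subtract the trajectory's own mean so that
only shape, not porosity level, drives a grouping.

Two auxiliary scalars: OCL/EL relative thickness is the layer's area
percentage of total sector cortex area; for hoatzin chicks of unknown age,
age is estimated by inverting the linear mass-age relation
y = 9.61 + 5.63x (mass in g, age in days posthatching), valid only above
the 9.61 g hatchling intercept.

### Geometry choices

The circumference-following quadrant separators are not fully specified by
the protocol's verbal description; this package uses blended curves — the
separator at fraction *t* interpolates point-by-point (in arc-length
parameterisation) between the inner and outer boundary — which reproduces
curved separators on curved cortices and degenerates to straight chords on
straight-sided sectors. A `"chord"` fallback is available. "Equal length"
side sections are equal *arc length*, since real radial sides curve.
Pixel membership uses centre-in-polygon; areas are pixel counts times
`pixel_size^2`. These choices make quadrant areas partition the sector
area exactly (to float precision) at the polygon level and to within
discretisation at the raster level.

Whether OCL/EL should be excluded from quadrant denominators or merely
withheld from the numeric analyses is ambiguous in the source protocol;
exclusion is the default here (`exclude_layers = TRUE`) and toggleable.

## The synthetic generators

`generate_section()` renders a circular cross-section blueprint: medullary
cavity, cortex ring, optional EL/OCL rims, remodelled patches, and pores
following a radial porosity law (relative depth → target pore area
fraction). Pores are non-overlapping disks placed on a jittered polar
lattice:

* rows are stratified at quarter-depth breaks so no row straddles a
  quadrant band;
* each row's disk areas are rescaled so the row hits the slab-averaged
  target fraction exactly, making the blueprint law the analytic ground
  truth (`expected_quadrant_rpp()` integrates it with annulus-area
  weights);
* the jitter amplitude shrinks to zero as the target fraction approaches
  the lattice packing limit, preserving the hard-core property at all
  feasible fractions (the constructor rejects laws above 0.72, the
  practical ceiling of this packing).

The default pore radius (2.2 px, sd 0.55) keeps pore diameter small
relative to one quadrant's radial depth, mirroring real primary canals
(tens of µm) against cortices of hundreds of µm to mm; much larger pores
would alias pore rows against the quadrant bands. Validation runs use
cavity radius 80 px and cortex thickness 140 px (about 460 px sections),
where measured mean RPPs track the analytic target to well under 2
porosity points; accuracy improves with resolution (checked by a
resolution-doubling test).

What the generator does **not** emulate: irregular (non-circular) cortex
outlines, anisotropic or branching canal networks, gradual porosity
textures within a pore row, imaging noise, or segmentation error. Passing
round-trip tests therefore demonstrates the correctness of the geometry
and bookkeeping, not robustness to segmentation quality on real
photomicrographs.

`generate_rpp_dataset()` simulates the statistical structure downstream:
group-specific polynomial mean trajectories over quadrant index 1..4,
independent Gaussian sector noise (truncated to [0, 100]), per-quadrant
missingness concentrated in the inner quadrants with an a→b coupling
(P(b missing | a missing) ≥ 0.7, the a-present conditional solved to
preserve b's marginal rate where feasible) mimicking perimedullary
remodelling spreading outward, and metadata (ages, elements, strategies,
specimens). The default design is four parallel quadratic groups whose
adjacent curves sit 5 residual standard deviations apart — residual sd
meaning the sd of the mean RPPs the models are actually fitted to,
`noise_sd / sqrt(n_sectors)` — with 20 elements per group: a clean
four-group world against which the grouping engines are validated.

## Trajectory distances

RPPs are treated as 2-D point sequences (quadrant position, porosity in
raw percent; no axis rescaling). Missing points are dropped, positions
retained — no imputation.

* **DTW**: minimal sum of Euclidean point distances over monotone warping
  paths, unconstrained, unnormalised.
* **Edit distance**: Levenshtein dynamic program; two points match when
  both coordinate differences are within `eps` (default 5 porosity
  points/quadrant units); insertion, deletion and substitution cost 1.
* **LCSS**: longest common subsequence under the same eps-matching,
  maximised over a symmetric grid of translations in both dimensions
  (default 20 per sign per dimension spanning the quadrant range and the
  full porosity scale); similarity is the count over the shorter length.

The tolerance and translation-grid defaults are explicit package choices —
the measures are parameter-sensitive (LCSS especially so) and no
authoritative settings exist; they are recorded in outputs and should be
reported alongside results. All three dynamic programs are validated
against exhaustive enumeration (all warping paths; memo-free recursion;
subsequence enumeration over the translation grid) on trajectories up to
length 4.

## Grouping engines

* `kmeans_cluster()`: Lloyd iterations from 100 random initialisations
  (seeded), minimal within-cluster sum of squares kept, complete RPPs
  only, raw porosities (no standardisation).
* `hclust_complete()` / `cut_tree()`: complete-linkage agglomeration on a
  distance matrix, validated against a naive cubic-time oracle; trees cut
  at 3-5 groups in typical use.
* `fit_gbtm()`: the package's model core — a k-component mixture of
  polynomial mean trajectories over quadrant index with Gaussian residuals
  and a shared variance, fitted by EM. Each start is seeded k-means++
  style and warmed with a short EM burst; the best start by log-likelihood
  runs to convergence (tolerance 1e-8, cap 500 iterations). The residual
  model is Gaussian, not the zero-inflated Poisson of the criminology
  lineage of group-based trajectory modelling: porosity is a continuous
  percentage, not an event count. Exact numerical replication of
  count-model fits is therefore out of scope by design.

Model selection (`gbtm_select()`) scans group numbers 1..5 and polynomial
degrees 1..3, tabulating AIC (−2ℓ + 2p), BIC (−2ℓ + p log n) and
leave-one-out CVE, and repeats the scan across seeded runs, flagging the
modal best configuration. The parameter count is p = k(degree+1) + (k−1)
+ 1.

**CVE scoring.** For each fold the model is refitted without the held-out
element (warm-started from the full-data solution) and the element is
scored as the mean squared deviation from its posterior-weighted predicted
curve — with each point's posterior computed from the trajectory's *other*
points only. Computing posteriors from the full held-out trajectory makes
CVE decrease monotonically in k (an extra component is always rewarded by
the very point that selected it), which inverts the statistic's purpose;
the point-level scheme restores honest out-of-sample behaviour (overfit
k on homogeneous data scores worse than the true k, on average).

Known behaviour: AIC can still buy a sliver component on some data draws
(a generic property of AIC on mixtures); BIC is the stable criterion at
these sample sizes, and the modal vote across criteria and repetitions is
what the selection reports.

The Formann-style floor `formann_min_sample()` returns 2^d for d
parameters. The narrative restatement of this rule in the source protocol
quotes 32 and 64 for four and five quadrants, which is 2^(d+1); the
function follows the formula and this discrepancy is documented rather
than resolved.

## Downstream statistics

* **Alignment** (`align_labels()`): optimal one-to-one group matching by a
  Hungarian assignment on the contingency table — an operationalisation of
  matching clusters "by composition"; unmatched groups (unequal k) count
  as disagreement. Validated against the permutation maximum for k ≤ 5.
* **Congruence** (`congruence_report()`): pairwise aligned agreement,
  per-method overall congruence (sum of its pairwise percentages), and
  consensus tiers (share of elements identically grouped by all M
  methods, exactly M−1, ...) after aligning every method to a reference
  method (default the first, configurable). The reference choice can move
  tier percentages by a few points; it is recorded in the report.
* **Dissociation** (`dissociation()`): per specimen, "0" when all bones
  share one group, else ascending hyphen-joined bone counts per group
  ("1-3", "1-2-3", ...).
* **Membership regression** (`multinom_fit()`, `stepwise_select()`):
  multinomial logistic regression of labels on age, bone type,
  developmental strategy and/or specimen, via `nnet::multinom`. Backward
  stepwise drops whole predictors (all levels at once) by AIC; AICc
  (= AIC + 2p(p+1)/(n−p−1), NA when n ≤ p+1) is tabulated for every
  visited model together with PM%, the percentage of elements whose modal
  predicted membership matches the actual one. Complete separation — easy
  to produce in small designs where strategy splits a cohort perfectly —
  is detected by a coefficient-magnitude check and refitted with a tiny
  ridge penalty (1e-6), flagged in the result.

## Numerical and degenerate-input policy

Ties break toward the lowest index throughout; every stochastic routine
takes an explicit seed and records it; empty mixture components restart
the EM start; single-class regression responses, non-symmetric distance
matrices, out-of-range cuts and unmapped elements raise errors rather
than warnings. Nothing is silently imputed: rejected table rows, excluded
trajectories and separation fallbacks are all surfaced in attributes,
reports or flags.

## Validation problem sizes

The shipped validation suite runs entirely on synthetic material: ten
section blueprints (porosity laws spanning 0-60%, monotone and stepped)
for the measurement round trip at 460 px; 100 random trajectory pairs per
distance oracle; 50 random matrices (n ≤ 7) for the linkage oracle; 50
random labelling pairs for the alignment oracle; the default four-group
design (n = 80) for GBTM selection and congruence; 20 seeded replicates
(n = 150) for the stepwise-elimination check and one n = 200 draw for
coefficient recovery. These sizes were chosen to exercise every code path
at desk scale; all reported numbers are recomputed at run time by
`scripts/acceptance.R`.

## Limitations

* Classes are inputs: the package measures labelled rasters and does not
  segment photomicrographs.
* Two-dimensional areal measurement only; no volumetric (µCT) support.
* The GBTM noise model is Gaussian with shared variance; heteroscedastic
  or count-type porosity data would need a different residual family.
* LCSS results depend strongly on eps and the translation grid; treat its
  groupings as exploratory.
* The synthetic world is circular and cleanly segmented; conclusions
  about robustness to real histological noise cannot be drawn from it.
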