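# rppbone

Quantitative bone histomorphometry for developmental inference: **radial
porosity profiles (RPPs)** of limb-bone mid-shaft cross-sections, from
raster measurement to trajectory grouping and membership statistics.

Cortical bone grows outward, so a transverse section preserves a radial
time axis: the inner cortex is the oldest posthatching record, the
periosteal surface the youngest. Primary vascular porosity tracks local
deposition rate, which makes the radial porosity gradient a frozen growth
trajectory — readable in extant juveniles and in fossils alike. `rppbone`
is written for osteohistologists who want to turn labelled section images
into four-point porosity trajectories and analyse those trajectories for
developmental strategy (altricial vs precocial growth), ontogenetic stage
and skeletal dissociation.

## What it computes

* **Measurement.** Porosity per radial quadrant
  `P = 100 · V / (Q − excluded)`, where `V` is primary vascular area, `Q`
  quadrant area, and `excluded` covers secondary remodelling, the outer
  circumferential layer and the endosteal lamellar layer; quadrants whose
  primary record is mostly obliterated become missing values. Mean RPP
  per element: quadrant-wise average over up to three measurement
  sectors, `RPP = (ΣPa/S, ΣPb/S, ΣPc/S, ΣPd/S)` with available-case
  divisors. Sector/quadrant polygons are built on the section itself
  (arc-length quartering of the radial sides, circumference-following
  separators).
* **Trajectory grouping.** Four engines on the RPP set: restarted
  k-means; complete-linkage hierarchical clustering on DTW, edit-distance
  or LCSS distance matrices (missing-point tolerant); and group-based
  trajectory modelling — a k-component mixture of polynomial mean curves
  with Gaussian residuals fitted by EM, selected by AIC, BIC and
  leave-one-out cross-validation error over 1–5 groups and degrees 1–3.
* **Membership statistics.** Hungarian label alignment and cross-method
  congruence (pairwise, overall, consensus tiers), skeletal-dissociation
  signatures per specimen ("0", "1-3", "1-2-3", ...), and multinomial
  logistic prediction of memberships from age, bone type and
  developmental strategy with backward AIC selection, AICc and PM% (the
  share of elements whose predicted membership matches the actual one).
* **Synthetic ground truth.** Seeded generators for labelled
  cross-sections (hard-core disk packing following a radial porosity law,
  analytic per-quadrant expectations) and for RPP datasets with known
  group structure, so the entire pipeline is testable without any
  external data.

## Worked example

Generate a synthetic section whose porosity falls from 40% at the
endosteal margin to 10% periosteally, measure it, and model a synthetic
four-group dataset:

```r
library(rppbone)

bp  <- section_blueprint(cavity_radius = 80, cortex_thickness = 140, seed = 2)
sec <- generate_section(bp)
res <- measure_section(sec$image, place_sectors_auto(sec$image, 3))
res$mean_rpp
#> RPP (Pa-Pd, 3 sectors):  36.45  29.24  20.52  13.43
round(expected_quadrant_rpp(bp), 2)
#> [1] 36.02 28.58 21.12 13.64
```

The measured mean RPP reproduces the blueprint's analytic expectation to
well under one porosity point per quadrant: `P_a` ≈ 36% in the oldest,
most vascularised inner quadrant, declining to ≈ 13% at the periosteal
surface — the profile of a still fast-depositing juvenile cortex.

```r
sim  <- generate_rpp_dataset(dataset_design(seed = 1))
rpps <- rpp_wide(sim$table)
fit  <- fit_gbtm(rpps, k = 4, degree = 2, seed = 1)
fit
#> GBTM: 4 groups, polynomial degree 2, n = 80
#> logLik -612.247  AIC 1256.493  BIC 1294.605  sigma 1.159
#> group sizes: 20 20 20 20
```

The mixture recovers the four planted trajectory groups exactly (20
elements each); `sigma` ≈ 1.16 matches the design's residual scale
(sector noise 2 averaged over 3 sectors). `gbtm_select(rpps)` scans
groups 1–5 × degrees 1–3 and flags this configuration as the modal best
across AIC, BIC and CVE; `congruence_report()`, `dissociation()` and
`stepwise_select()` take the grouping downstream.

A thin command-line pipeline wraps the same functions:

```sh
Rscript inst/cli/rpp.R simulate --config cfg.yaml --seed 4 --out run1
Rscript inst/cli/rpp.R cluster  --config cfg_cluster.yaml --out run2
```

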