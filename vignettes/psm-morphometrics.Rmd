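---
title: "Quantifying presomitic mesoderm morphogenesis from labelled 3D cell ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying presomitic mesoderm morphogenesis from labelled 3D cell ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmmorph)
```

## The biological problem

During posterior body elongation in the axolotl, presomitic mesoderm (PSM)
arises from neuromesenchymal progenitors of the posterior neural plate.
These cells collect in a posterior progenitor zone (PZ) at the tail-bud tip,
perform an anterior turn that is peculiar to tailed amphibians, and stream
anteriorly on either side of the neural tube and notochord until they
segment into somites. Grafting GFP-labelled posterior neural plate into
unlabelled host embryos, clearing the tissue optically and reconstructing
the labelled cells in 3D turns this process into a quantitative object:
every labelled cell has a centroid, a fitted ellipsoid, a region
(PZ, posterior/medial/anterior PSM, somite), and the ensemble has extents,
volume, density and cohesion.

`psmmorph` implements the measurement side of such a study — moment-based
ellipsoid fitting, orientation classification, mitotic spindle orientation,
per-section pairwise cohesion, closest-neighbour density, tissue extents and
volume, and the relative displacement metric $d_{rel}$ — together with a
synthetic tail-bud generator whose ground-truth parameters are the published
per-region statistics. Because no raw image data are deposited with the
study this package follows, the generator is also the package's test bed:
every estimator is validated by recovering known generating parameters at
the study's sample sizes.

## Coordinate frame and data model

All computations use a right-handed orthonormal embryo frame
(`axis_frame()`): $x$ = anteroposterior (AP, positive posterior), $y$ =
mediolateral (ML, positive right), $z$ = dorsoventral (DV, positive
dorsal), origin at the anterior-most body point, midline at $y = 0$. All
lengths are µm, volumes µm³.

A snapshot (`psm_snapshot()`) is a tibble with one row per labelled cell —
centroid, ellipsoid semi-axes $a \ge b \ge c$, unit long-axis vector,
volume, Sox2 status, graft origin, region and filopodium lengths — plus the
frame, the stage and any mitotic events as attributes. Snapshots round-trip
through a fixed TSV dialect (`read_cell_table()`/`write_cell_table()`), and
cells can also be extracted from 3D label images
(`cells_from_label_stack()`).

## The measurement operations

**Ellipsoid fitting.** `fit_ellipsoid()` takes the eigen-decomposition of
the second central moment tensor of a point set; semi-axes are
$\sqrt{5\lambda_k}$, exact for a uniformly filled solid ellipsoid (for a
solid ellipsoid the second moment along a principal axis is $a_k^2/5$).
Axis vectors follow a deterministic sign convention (largest-magnitude
component positive). Points must be non-coplanar; rotation equivariance is
tested to $10^{-6}$.

**Shape and orientation.** The "cellular coefficient" is the long/short
aspect ratio $a/c$ (`aspect_ratio()`). `classify_orientation()` assigns
each cell to AP, ML or DV by the largest $|e_a \cdot \text{axis}|$;
cells with $a/c <$ `min_ar` (default 1.3) are left unclassified because a
near-spherical cell has an unstable long axis. The 1.3 default also
explains why per-region orientation percentages need not sum to 100%.

**Spindle orientation.** A division's spindle vector joins its two
centriole points; it counts as AP-oriented when its folded angle to the AP
axis is at most `cone_half_angle` (default 30°). Under uniformly random
directions the expected AP fraction is $1 - \cos 30° = 13.4\%$, a useful
baseline: observed fractions of 1.4–12.1% sit at or below it, which is why
oriented division is not a plausible driver of AP elongation. A 30° cone is
the package's own choice of criterion (none is standard); it is
configurable, and `spindle_ap_fraction()` is provably monotone in the cone
angle.

**Cohesion.** Group cohesion is measured exactly as in sectioned material:
cells are partitioned into 80 µm half-open slabs along the AP axis
(`assign_sections()`; a centroid rule, so counting is exact and
thickness-invariant — a deliberate simplification of physical sections that
cells can span), and every unordered pair of labelled cells *within* a
section contributes its full 3D centre-to-centre distance
(`pairwise_cohesion()`). Whether in-plane 2D or 3D distances are the right
reading of sectioned measurements is ambiguous; 3D is the default and a
`planar = TRUE` mode is provided. The summary is the exact sample median
plus the fraction of pairs closer than 25 µm.

**Density.** `nearest_neighbour_density()` reports each cell's distance to
its closest neighbour within its group; groups are regions by default (the
sphere-grouping radius of the original analysis is not stated, so grouping
degenerates to region membership).

**Tissue measures.** `labelled_extents()` projects ellipsoid surfaces (not
centroids) on the frame axes, so a single cell has nonzero size;
`labelled_volume()` rasterizes ellipsoids with union semantics (overlaps
counted once; halving the voxel changes the result by under 2% on
ensembles of a few hundred cells); `growth_phase()` labels stage intervals
isovolumetric/volumetric/shrinking with a relative tolerance of 0.15 —
wide enough to call biological constancy, narrow enough to separate it from
doubling; `midline_crossing_fraction()` counts cells strictly across the
midline plane opposite the graft side; and `relative_displacement()`
computes $d_{rel} = a/b$, with $b$ the arc length of the ventral body
contour and $a$ the arc length to the nearest-point projection of the
label centroid (ties to the smallest arc length; invariant under rigid
motion and uniform scaling).

**Group comparisons.** `compare_groups()` is a one-way ANOVA from explicit
between/within sums of squares (cross-checked against `aov()` in the
tests), with Holm-adjusted pairwise t tests. Holm was chosen over Tukey
because it is valid without distributional assumptions and the original
analyses report only omnibus stars. Simulated type-I error is checked to be
near nominal.

## The synthetic generator: what it emulates

`generator_config()` holds the generating parameters; its defaults *are*
the study conditions:

* **Counts** (per stage): labelled mesodermal cells 527 / 1095 / 1232 /
  1989 and neural (Sox2⁺) cells 0 / 27 / 78 / 1 at stages 19 / 22 / 28 /
  30. The split of each total across regions follows the qualitative
  staging (stage 22: PZ bulge plus nascent posterior stream; stage 30:
  stream from PZ through six somites).
* **Geometry**: the labelled strand runs along a configurable arc (spline
  control points; straight by default) with arc length 300 / 500 / 950 /
  1200 µm, and tube cross-sections chosen so the stage-30 strand has a
  near-constant DV height of about 140 µm. The embryo body-length schedule
  interpolates linearly from 2.1 mm (stage 14) to 9.3 mm (stage 40) —
  only the end points are published.
* **Shapes**: per-region aspect ratios from a log-normal parameterised by
  the published mean/SD (2.33/0.70 PZ, 2.78/0.67 posterior, 2.26/0.68
  medial, 2.37/0.71 anterior, 3.03/1.31 somites), truncated at 1; the mid
  axis $b$ is uniform in $[c, a]$; volumes are log-normal with mean 8000
  µm³ in the stage-22 PZ, halving to 4000 µm³ in all later PSM/somite
  regions (the halving rule is published; the absolute level is the
  package's choice of a realistic yolk-rich mesenchymal cell of ~25 µm).
* **Orientation**: per-region class probabilities (e.g. PZ 48% ML, medial
  PSM 44% AP, somites 46% DV / 33% AP) are realised *jointly* with the
  shape threshold: an "unclassified" draw receives an aspect ratio below
  `min_ar`, a classified draw receives one above it and a long axis uniform
  in the arg-max spherical region of its class. The default unclassified
  probability equals the below-threshold mass of the region's shape
  distribution, so the marginal shape distribution is undistorted and the
  classifier recovers the configured vector exactly in expectation.
* **Spindles**: per-stage AP fractions 5.9 / 1.4 / 12.1 / 4.4%, realised by
  drawing inside/outside the same 30° cone the classifier uses, so
  generation and classification agree by construction.
* **Filopodia**: Poisson counts per cell (mean 1.6 in posterior/medial PSM,
  3.0 in anterior PSM — more but shorter — and 0.6 in PZ and somites, so
  only the PSM regions have a majority of cells with at least one), with
  log-normal lengths (mean 6 µm posteriorly, 4 µm anteriorly, truncated to
  (0, 40] µm).
* **Tissue volume schedule**: $[V, V, 2V]$ across stages 22/28/30. Note
  this is a tissue-level schedule, deliberately independent of the summed
  cell volumes: the published cell counts and the cell-volume halving are
  mutually inconsistent with exact tissue-volume constancy, which is
  resolved by letting extracellular space carry the difference.

**Cluster mode and cohesion calibration.** Small actin-reporter grafts
(~20 cells) appear as one tight labelled clone per region;
`lifeact_config()` emulates them with clone sizes 14 / 9 / 21 / 11 / 18
chosen so that three pooled clones reproduce the published per-region
pairwise-distance counts (246 / 92 / 437 / 150 / 446). Each clone is an
isotropic Gaussian cloud about an anchor at section mid-depth. Two
conventions control the sampling variance of this design, in which a few
dozen cells generate hundreds of correlated pairs: the clone's *empirical*
dispersion is standardized to the calibrated scale (not just its
expectation), and the anchor phase relative to the section grid is fixed.
Both conventions are mirrored exactly in the calibration simulation:
`calibrate_cohesion_sigma()` root-solves a Monte-Carlo estimate of the
in-section median pairwise distance (sectioning discards pairs spanning a
cut, biasing the observed median below the unconditional Gaussian value, so
a closed form is not available) under a fixed internal RNG scope, making
configuration construction deterministic.

**Density groups.** The closest-neighbour scales (~30 µm from PZ to
anterior PSM, ~25 µm in the youngest somite) are realised by
`generate_density_groups()`: $n$ cells uniform in a sphere of radius
$R = r_m (n / \ln 2)^{1/3}$, the Poisson-process radius whose median
nearest-neighbour distance is $r_m$. Ensemble snapshots instead place
cells uniformly in the region tube, whose density follows from the
published counts and tissue dimensions; the two are intentionally separate,
because packing both constraints into one ensemble is over-determined.

**Graft series and perturbations.** `generate_graft_series()` realises the
substream logic: median-origin cells reach the furthest anterior, lateral
ones stay in PZ/posterior PSM, with a deterministic "leader" cell pinned at
each origin's anterior boundary so the ordering holds for every seed; only
median (and whole-plate) grafts seed the contralateral side.
`apply_epidermis_removal()` models the loss of the lateral epidermal
barrier as a deterministic affine widening of the ML dispersion of PZ and
posterior-PSM cells on the deprived side(s), leaving the anterior PSM and
the contralateral side untouched — which is exactly the fingerprint the
density comparison (`compare_epidermis_conditions()`) should and does
detect.

## What the generator does *not* emulate

The spatial point process of real PSM cells is unknown; Gaussian clones,
uniform tubes and Poisson spheres are stand-ins with the right first-order
statistics, not mechanistic models. There is no force-based mechanics, no
cell migration over time (snapshots are independent draws, not a tracked
lineage), no imaging noise or point-spread function, and no segmentation
error. Passing recovery tests therefore shows that the estimators are
correct and well-calibrated at realistic sample sizes — not that they are
robust to segmentation artefacts in real images.

## Numerical choices and degenerate inputs

Ellipsoid fits require ≥ 4 non-coplanar points and report degenerate label
geometry explicitly; coincident centrioles are excluded from the spindle
denominator with a warning (an empty event set yields `NA`, not 0);
sections are half-open so boundary cells are never double-counted; region
assignment at an exact breakpoint goes to the more posterior region;
outline projection ties resolve to the smallest arc length; rasterization
uses voxel-centre membership at 2 µm by default (1 µm roughly halves the
discretisation error). Every stochastic routine takes an explicit seed and
scopes it locally (`withr::with_seed`), so equal `(config, seed)` give
bit-identical snapshots without touching the caller's RNG state.

## Problem sizes used in the tests

The test-suite recovery runs use the study's own sample sizes: 5000 cells
per region for shape/orientation recovery, 5000 division events, ~2000
filopodia, 100 000 directions for the uniform baselines, and the published
pairwise-distance counts (three pooled clones) for cohesion. Property
checks (brute-force equivalence, rotation invariance, round trips) run on
groups of ≤ 50 cells where exhaustive enumeration is exact.

## A worked example

```{r example, eval = FALSE}
library(psmmorph)

# one small-clone snapshot at stage 28, sectioned and summarised
cfg  <- lifeact_config()
snap <- generate_stage_snapshot(cfg, 28, seed = 1)
sec  <- assign_sections(snap, "AP", 80)
pairwise_cohesion(sec[sec$region == "medial_PSM", ])

# the full pipeline
res <- run_morphometry(seed = 1)
res$summary
```

## Known limitations

Anisotropic voxels are unsupported in label-image extraction; extents use
an upper-bound support radius for the transverse axes (exact for
spheroids); `run_morphometry()` is a fixed orchestration rather than a
plugin pipeline; and the ANOVA treats cells as the experimental unit
(pooling across embryos), as the published figure legends imply — an
embryo-level mixed model would be the conservative alternative when embryo
identities are available.
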