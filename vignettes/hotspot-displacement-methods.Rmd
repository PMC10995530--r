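---
title: "Hot-spot displacement biomarkers in 3D PET: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hot-spot displacement biomarkers in 3D PET: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biomarkers

During solid-tumor growth, the most metabolically active tissue tends to
drift from the lesion core toward its periphery, so the position of the
PET uptake hot spot inside the lesion carries prognostic information
beyond the uptake values themselves. `pethotspot` quantifies this
displacement with two dimensionless distances computed on the segmented
metabolically active volume:

* **NHOC** — the Euclidean distance (mm) from the hot-spot location to
  the lesion centroid, divided by $R_{eq} = (3V/4\pi)^{1/3}$, the radius
  of the sphere with the lesion's volume $V$;
* **NHOP** — the minimum distance from the hot spot to the lesion
  perimeter, normalized the same way. A 2D single-slice predecessor
  (nSPD, computed on the axial slice holding the hot spot and
  normalized by the equal-area circle radius) is provided for
  comparison; the 3D form is recommended.

Each comes in two variants depending on the hot-spot locator: the
SUVmax voxel, or the SUVpeak center (the in-lesion position maximizing
the mean SUV over a 1 cm$^3$ sphere, radius $\approx 6.2035$ mm; the
sphere may average image voxels outside the lesion, and parts beyond
the grid are dropped from the average). On a perfect sphere
NHOC + NHOP = 1 and the two are perfectly anticorrelated; real lesions
break the identity, which is why both are reported. NHOC can exceed 1
for elongated lesions (the centroid-to-hot-spot distance may exceed
$R_{eq}$); NHOP cannot, beyond voxelization effects, since the distance
to the perimeter is bounded by the inradius. Published cohort tables
nevertheless report NHOPmax values up to about 1.26; the convention
producing values above 1 is not documented, so this package asserts
NHOP $\le 1$ plus a half-voxel tolerance and leaves the discrepancy
noted rather than guessing at a reproduction.

## Pipeline

The surrounding pipeline mirrors standard PET radiomics practice:

1. **Segmentation** (`threshold_segment()`): isocontour at a fraction
   (default 40%) of the SUVmax found *inside the seed VOI* — the
   threshold is lesion-relative, making the mask invariant to global
   intensity scaling. The mask is restricted to the 26-connected
   component containing the SUVmax voxel. Morphological closing
   (`close_mask()`, ball element, radius in mm) optionally swallows
   cold necrotic cores; toggling this step is how necrosis-in /
   necrosis-out comparisons are run. The closing radius is not
   standardized anywhere; the pipeline default of twice the largest
   voxel spacing removes noise-induced holes and pits, while swallowing
   an actual core of radius $r$ needs a radius comfortably above $r$
   (a radius exactly equal to $r$ is marginal against discretization
   and can leave a carved center).
2. **Preprocessing** (`gaussian_filter()`, `resample_volume()`,
   `discretize()`): isotropic gaussian postfiltering specified in mm
   (per-axis SD in voxels is `sigma_mm / spacing`; reflect padding
   avoids edge darkening), trilinear resampling onto a voxel-center
   aligned grid covering the input extent (nearest-neighbor for
   masks), and fixed-bin-width discretization. The default gray-level
   setup is 192 levels over [0, 60) SUV; the bin width is the exact
   quotient 60/192 = 0.3125 SUV (a displayed value of "0.31" is read
   as rounding, since 0.31 × 192 ≠ 60). Out-of-range SUVs clamp into
   the edge bins so the level count stays fixed.
3. **Features** (`extract_features()`): SUVmin/max/peak/mean, MTV, TLG
   = MTV × SUVmean, sphericity $\pi^{1/3}(6V)^{2/3}/A$, the four
   displacement features, and six texture features — GLCM joint
   entropy (log10) and inverse difference moment, GLRLM short/long run
   emphasis, GLSZM low/high gray-level zone emphasis. Lesions with
   diameter (2$R_{eq}$ by default; a Feret option exists) below 12 mm
   cannot host the SUVpeak sphere: the peak-based entries are copied
   from the max-based ones and flagged (`peak_fallback_used`).

### Numerical conventions worth knowing

* All distances are physical (mm); voxel indices are 0-based with the
  voxel-center convention `world = origin + index * spacing`, so
  anisotropic grids are handled throughout. NIfTI rotation matrices
  are ignored on input — every feature is rotation-covariant.
* **Perimeter distance.** The perimeter of a voxelized mask is taken
  to be the union of its exposed voxel faces, and NHOP uses the exact
  point-to-face distance (`method = "surface"`). Point-set shortcuts —
  nearest outside voxel center, nearest in-mask boundary voxel
  center — are offered and agree within a voxel diagonal, but both
  carry a systematic half-to-one-voxel bias (centers sit strictly
  inside or outside the surface), which matters when validating
  against analytic phantoms at 1 mm resolution.
* **Centroid.** Unweighted over mask voxels (the lesion's geometric
  center, matching "tumor centroid"); an intensity-weighted variant
  was considered and rejected because it would entangle NHOC with the
  uptake distribution it is meant to complement.
* **Ties.** Hot-spot ties are broken by the smallest linear array
  index and reported; this makes every output deterministic.
* **Sphericity surface.** `voxel_faces` counts exposed faces (exact
  for boxes, ~50% area overestimate for spheres, giving
  $(\pi/6)^{1/3} \approx 0.806$ for any cube); `mesh` (default)
  triangulates the 0.5 isosurface of a lightly smoothed mask
  indicator by marching tetrahedra (six tetrahedra per cell sharing
  the main diagonal), which reproduces a 20 mm digital ball's area to
  within about 1%. Very small masks that smooth below the 0.5 level
  fall back to the binary field.
* **Texture aggregation.** One matrix per family pooling all 13 unique
  3D directions at distance 1 (GLCM counts both orderings, so the
  matrix is symmetric); gray levels in the emphasis formulas are the
  1-based discretized levels. Published software does not print its
  aggregation conventions, so the package's own are pinned by
  brute-force oracle tests.

## Statistics layers

**Robustness.** `bland_altman()` reports bias (mean of B − A, sample
SD with n − 1), 95% limits of agreement (±1.96 SD), and relative
variants, since SUV differences grow with SUV magnitude.
`robustness_report()` compares features on a common scale —
|bias| / mean |feature| and LoA width / mean — which is how "feature X
is more robust than feature Y" statements are made concrete here,
threshold-free. `spearman_matrix()` gives |Spearman r| with a
complete-linkage clustering order on 1 − |r| (constant features yield
missing correlations, distance 1). `icc_oneway()` implements the
one-way random-effects, single-score agreement ICC
$(MS_B - MS_W)/(MS_B + (k-1)MS_W)$ on top of a base-R ANOVA
decomposition.

**Survival.** Kaplan–Meier estimation and log-rank testing delegate to
the survival package (hypergeometric tie handling). Cutoff selection
(`maxstat_cutoff()`) is maximally selected rank statistics with
log-rank scores $a_i = \delta_i - \hat H(t_i)$ (Nelson–Aalen at the
follow-up time): at every admissible split the centered score sum is
standardized by its exact permutation variance, and the maximizing
cutpoint is returned. Because the cutoff is optimized, the naive
log-rank p-value is invalid; the p-value comes from seeded permutation
of the feature values (default 1000), re-maximizing per permutation —
assumption-free and directly testable for calibration, in contrast to
asymptotic maximum bounds. `minprop` (default 0.10) keeps both groups
at a minimum fraction of the cohort, since unrestricted extreme splits
make the standardized statistic degenerate; 0 admits all cutpoints.
The direction sign ("+": above-cutoff unfavorable) is set by comparing
group KM medians, falling back to the excess-mortality score sign when
both medians are undefined. The reported C-index is Harrell's, with the
feature as an increasing risk score (values below 0.5 mean the feature
is protective as coded), pairs usable when the earlier time is an
event, and ties counting one half. `risk_categories()` combines two
dichotomized features into 0/1/2 unfavorable states with pairwise
log-rank tests and Benjamini–Hochberg adjustment. Cox modeling is
deliberately out of scope. A pooled-cohort common cutoff is obtained by
running `maxstat_cutoff()` on the pooled records and applying the
resulting cutoff per subgroup.

## The synthetic generators

`make_phantom()` builds the only ground truth the package can be
validated against without patient data: an ellipsoidal lesion (uniform
plateau, default 4 SUV) on low background (0.5 SUV), a gaussian
hot-spot bump (default amplitude 4 SUV, SD 3 mm) centered at radial
fraction $f$ of the center-to-surface distance along a chosen
direction, an optional cold spherical core (1 SUV, 8 mm) at the
center, and additive gaussian noise (default SD 0.2 SUV, roughly 5% of
lesion uptake). Defaults model a 20 mm-radius lesion on a 57³ grid of
1 mm voxels; the odd grid size puts the lesion center on a voxel
center, so phantom geometry is not confounded by a half-voxel offset.
Two deliberate design choices:

* the bump is added only inside the ellipsoid, so the analytic
  ellipsoid is exactly the ground-truth 40%-isocontour mask (the
  background stays far below threshold and a surface hot spot cannot
  bleed the contour outward);
* in necrotic phantoms the hot spot is constrained to the viable rim,
  $f \ge (r_{core} + \sigma_{bump})/R$ — peak uptake cannot sit inside
  dead tissue. This constraint *is* the mechanism by which necrotic
  lesions exhibit higher NHOC and lower NHOP than matched controls,
  and the package's necrosis-contrast checks exercise exactly that.

What the phantoms do not emulate: PET reconstruction physics (Poisson
counting, PSF, sinogram artifacts), respiratory motion, scanner
heterogeneity, or textured intra-lesion uptake. Passing phantom tests
therefore validates the geometry and statistics of the implementation,
not clinical performance on real images.

`simulate_cohort()` draws per-subject features from independent
gaussians (defaults roughly matching an advanced-NSCLC cohort: NHOCmax
$\mathcal N(0.62, 0.29^2)$, NHOPmax $\mathcal N(0.26, 0.16^2)$, SUVmax
$\mathcal N(13.3, 7.2^2)$), exponential survival with hazard
$h_0 \exp(\sum_j \beta_j (x_j - \mu_j))$ (baseline median OS 15
months), exponential censoring (rate 0.01/month) plus a 60-month
administrative horizon. A zero horizon produces an all-censored,
flagged, degenerate cohort.

## Validation strategy and problem sizes

Every fast path is pinned to an independent brute-force oracle: the
SUVpeak convolution against an exhaustive double loop, the maxstat scan
against per-cutoff summation, Harrell's C against pair enumeration,
texture matrices against direct pair/run/zone counting (zones via an
igraph-based labeling), Spearman against rank-then-Pearson. End-to-end,
noise-free ball phantoms (radius 20 mm, 1 mm voxels) recover NHOC = f
and NHOP = 1 − f to within ±0.05 — about one voxel over $R_{eq}$, the
irreducible scale of voxel-center hot-spot localization. Null
calibration of the permutation p-value uses 500 simulated cohorts of
n = 100 with 1000 permutations each; power and direction checks use 25
cohorts at a hazard ratio of 2 per feature SD, and the filtering
robustness comparison uses 25 noisy phantoms at 2 mm voxels — sizes
chosen to keep the full validation suite in the minutes range on one
CPU while leaving the estimates' Monte-Carlo error well inside the
asserted margins. In the filtering comparison, re-segmentation couples
the mask to the smoothed image, so NHOC/NHOP shift too (down and up,
respectively — the same signed directions seen clinically); the robust
headline contrast is against SUVmax, while SUVpeak's advantage over
NHOP on this phantom family is real but small.

## Known limitations

* Perimeter values above 1 reported by other software cannot be
  reproduced (convention unknown; see above).
* The closing radius for necrosis inclusion is a free parameter; no
  published value exists to default to.
* Texture aggregation conventions differ between implementations;
  absolute texture values are comparable only within one convention.
* Phantom noise is additive gaussian, not reconstruction-realistic;
  robustness rankings on phantoms should be read qualitatively.
* Whole-body multi-lesion aggregation of NHOC/NHOP is out of scope.
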