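# pethotspot

Hot-spot displacement biomarkers (NHOC / NHOP) and a complete radiomic
feature-extraction and evaluation pipeline for 3D PET volumes in SUV
units.

## The problem

In [18F]FDG PET of solid tumors, the *position* of the uptake hot spot
inside the lesion — not just its value — reflects tumor biology:
aggressive growth pushes the most active tissue from the core toward
the periphery. Two dimensionless biomarkers capture this displacement
on the segmented metabolically active volume:

- **NHOC** = d(hot spot, lesion centroid) / R_eq — normalized
  hot-spot-to-centroid distance;
- **NHOP** = min d(hot spot, lesion perimeter) / R_eq — normalized
  hot-spot-to-perimeter distance (3D successor of the single-slice
  nSPD, which is also provided);

where R_eq = (3V / 4&pi;)^(1/3) is the radius of the sphere with the
lesion's volume, making both quantities independent of lesion size.
Each exists in a SUVmax-based and a SUVpeak-based variant (SUVpeak:
maximum mean SUV over a 1 cm³ sphere anchored in the lesion; lesions
under 12 mm diameter fall back to the SUVmax variants, flagged). High
NHOC / low NHOP — a hot spot near the edge — is the unfavorable
configuration.

The package is aimed at PET imaging researchers who want to compute
these biomarkers reproducibly, check their robustness to imaging
parameters, and evaluate their prognostic value, without depending on
GUI software:

- **Extraction**: NIfTI I/O with physical (mm) geometry; 40%-of-SUVmax
  isocontour segmentation with 26-connected component selection and
  optional morphological closing (necrotic-core inclusion); gaussian
  postfiltering, voxel resampling, fixed-bin-width discretization
  (192 levels over 0–60 SUV, width 0.3125); 17 per-lesion features
  (SUV statistics, MTV, TLG, sphericity, NHOC/NHOP variants, GLCM /
  GLRLM / GLSZM texture features).
- **Robustness statistics**: Bland–Altman bias and 95% limits of
  agreement (±1.96 SD), scale-normalized per-feature robustness
  reports, Spearman correlograms with hierarchical ordering, one-way
  single-score agreement ICC.
- **Survival statistics**: Kaplan–Meier, log-rank, maximally selected
  rank statistics cutoffs with seeded permutation p-values and
  direction signs, Harrell C-index, 3-category bivariate risk
  stratification with Benjamini–Hochberg adjustment, Wilcoxon rank-sum
  comparisons.
- **Synthetic ground truth**: digital ellipsoid phantoms with a
  displaced gaussian hot spot, optional cold necrotic core and noise;
  survival cohorts with known feature–hazard links. Everything the
  package claims is validated against these generators and against
  brute-force oracles.

## Worked example

```r
library(pethotspot)

# a 20 mm lesion, hot spot 60% of the way to the surface, SUV noise
ph   <- make_phantom(phantom_spec(hotspot_fraction = 0.6, seed = 42))
mask <- close_mask(threshold_segment(ph$volume, ph$seed), 2)
extract_features(ph$volume, mask)
#> <feature_vector>
#>   SUV min/mean/peak/max: 3.250 / 4.049 / 5.293 / 8.102
#>   MTV 33.4 cm^3, TLG 135.2, sphericity 0.9974
#>   NHOC max/peak: 0.6507 / 0.6007
#>   NHOP max/peak: 0.3263 / 0.3762
```

The phantom was built with the hot spot at radial fraction 0.6, and the
extracted NHOCmax is 0.65 with NHOPmax 0.33 — the displacement is
recovered to within the voxel-scale tolerance (on a sphere
NHOC + NHOP ≈ 1). MTV 33.4 cm³ matches the analytic ball volume
(33.5 cm³), and sphericity is ~1 as expected for a ball.

```r
# survival screening: cohort with a known hazard link (HR = 2 per SD)
co <- simulate_cohort(cohort_spec(n = 150, beta = c(nhoc_max = log(2)/0.29),
                                  seed = 42))
maxstat_cutoff(co, "nhoc_max", n_perm = 1000, seed = 42)
#> <cutoff_result> nhoc_max: cutoff 0.5847 (67/83), |T| = 5.472,
#>   perm p = 0.000999, direction +, C-index 0.652
```

The selected cutoff dichotomizes the cohort at NHOCmax ≈ 0.58; the
permutation p-value is significant, and the direction sign `+` says
high NHOC goes with poor survival — the direction the cohort was
simulated with.

A thin command-line front end over the same functions is installed at
`inst/cli/pethotspot` (`extract`, `robustness`, `correlogram`,
`survival`, `simulate`), reading NIfTI/CSV and writing CSV/JSON reports
that embed the full configuration for provenance.

## Package layout

- `R/volume.R`, `R/volume_io.R` — SUV volume / mask containers, NIfTI
  I/O, voxel-world geometry
- `R/preprocess.R` — gaussian filtering, resampling, discretization
- `R/segmentation.R` — isocontour segmentation, closing, lesion
  geometry
- `R/hotspot.R`, `R/features.R` — SUVmax/SUVpeak search, NHOC, NHOP,
  nSPD, sphericity, full feature vectors
- `R/texture.R` — GLCM / GLRLM / GLSZM features
- `R/robustness.R` — Bland–Altman, Spearman correlogram, ICC
- `R/survival.R` — KM, log-rank, maxstat cutoffs, C-index, risk
  categories, Wilcoxon
- `R/synthetic.R` — phantom and cohort generators
- `R/pipeline.R`, `inst/cli/pethotspot` — runnable pipeline and CLI
- `vignettes/hotspot-displacement-methods.Rmd` — models, conventions,
  design decisions, limitations
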