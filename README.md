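# trabecula

Trabecular bone micro-architecture and mechanical competence from 3D
gray-scale volumes: segmentation of clinical-resolution scans with an
automated region-growing (ARG) scheme, 3D histomorphometry by
skeletonization and sphere-fitting local thickness, apparent stiffness
by voxel micro-finite-element homogenization, and the statistical layer
that relates clinical-resolution structure parameters to micro-FE
mechanics.

## Who this is for

Researchers in bone imaging / osteoporosis who want to quantify
trabecular structure from micro-CT-grade or clinical-grade (CBCT,
HR-pQCT) volumes and ask how well clinical-resolution measurements
predict mechanical competence — and anyone who needs a fully synthetic,
seeded test bed for such pipelines.

## What it computes

**Segmentation.** For uncalibrated clinical-resolution volumes, ARG:
seeds from the attenuation distribution, 50 homogeneity thresholds
linearly spaced from the seed-intensity spread `t0` to `1.6 t0`,
region growth per threshold, and selection of the mask minimizing an
assessment score `w1·log(WCV) − w2·log(G²)` (pooled within-class
variance vs mean squared boundary gradient). For calibrated micro-CT
data, the between-class-variance (Otsu) threshold. Plus CNR
measurement.

**Histomorphometry** (all 3D): BV/TV (exact voxel ratio), Tb.Th and
Tb.Sp (mean sphere-fitting local thickness of bone / marrow, mm),
Tb.Sc (mean thickness of the mid-surface-skeleton complement: distance
between trabecular midlines, mm), Tb.N = 1/Tb.Sc (1/mm), Tb.Nd and
Tb.Tm (junction clusters and interior free ends of the voxel-wide
curve skeleton, per mm³).

**Micro-FE.** Each bone voxel becomes a linear isotropic 8-node
hexahedral element (E = 12 GPa, ν = 0.3). Six load cases under
kinematic uniform boundary conditions (surface nodes displaced by
u = ε·x) give the 6×6 apparent stiffness C from volume-averaged
element stress; engineering constants come from S = C⁻¹ with E3 the
maximum Young's modulus and Gmin the smallest shear modulus.

**Statistics.** Pearson correlations with Fisher-z 95% CIs, simple
linear regression (R², two-tailed p), SPSS-style stepwise multiple
regression (entry p ≤ 0.05, removal p ≥ 0.10; single-predictor R² and
two-predictor adjusted R²), Bland–Altman reproducibility, descriptive
statistics.

**Synthetic specimens.** Thresholded anisotropic Gaussian random
fields with controlled BV/TV, thickness scale and anisotropy, plus a
scanner simulator (PSF blur, detector block-averaging, noise,
intra-bone intensity heterogeneity) so the full study design runs in
silico, seeded and reproducible.

## Worked example

```r
library(trabecula)

# a 4.8 mm trabecular cube at 0.05 mm voxels, 20% bone volume
truth <- generateGroundTruth(PhantomSpec(targetBvtv = 0.2, seed = 7))
truth
#> BinaryVolume 96x96x96 @ 0.05 mm/voxel, BV/TV = 0.1999

# a clinical-resolution rescan (0.15 mm voxels, PSF, noise)
scan <- simulateScan(truth, ImagingSpec(outVoxelMm = 0.15, seed = 7))
scan
#> GrayVolume 32x32x32 @ 0.15 mm/voxel, range [-282, 1662]

# ARG segmentation of the rescan
seg <- argSegment(scan)
seg
#> ARGResult: 50 iterations, selected #1 (threshold 248.2), nested = TRUE

computeMetrics(seg@selectedMask)
#>       Tb.Nd     Tb.Tm     Tb.Sp     Tb.Sc     Tb.N     Tb.Th      BVTV
#> 1 0.8590133 0.7866753 0.6258178 0.6122245 1.633388 0.2225546 0.2250366

# micro-FE on a 2.4 mm cube of the fine-resolution truth
stiff <- homogenize(buildModel(extractCube(truth, 2.4)))
stiff
#> StiffnessResult: E1 = 0.311, E2 = 0.38, E3 = 0.5487 GPa; Gmin = 0.1387 GPa
```

The rescan's BV/TV (0.225) overestimates the ground truth (0.200) —
the partial-volume behaviour clinical scanners show against micro-CT —
and the anisotropic phantom is stiffest along axis 3 (E3 = 0.55 GPa at
20% bone volume, about 5% of the 12 GPa tissue modulus).

The full in-silico study — n specimens spanning BV/TV 0.05–0.45, fine
and clinical rescans, per-modality metrics, micro-FE, and all report
tables (correlations, regressions, stepwise, descriptives,
Bland–Altman) — is one call:

```r
res <- runStudy(studyConfig(nSpecimens = 6, masterSeed = 42))
res$reports$regressionE3   # R2 / p of E3 on every parameter x modality
```

`reproduceStudyTables()` recomputes the same report tables from any
stored per-specimen table (CSV/XLSX, configurable column mapping) and
can compare against printed reference values
(`inst/extdata/reference_study_tables.csv`) at two-decimal rounding.

A thin command-line front end with subcommands `generate`, `scan`,
`segment`, `morpho`, `fe`, `run-study`, `reproduce-tables` is installed
at `inst/scripts/trabecula-cli.R`.

## Documentation

The methods vignette (`vignettes/trabecular-bone-pipeline.Rmd`)
documents the models and their assumptions: the random-field phantom
and its calibration, the scan simulator, the ARG design choices and
the reasons behind them, the thickness/skeleton conventions, the KUBC
micro-FE formulation, the statistical conventions, and known
limitations.
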