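---
title: "Trabecular bone structure and stiffness: models and methods"
author: "trabecula package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trabecular bone structure and stiffness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Osteoporotic fracture risk depends not only on how much bone a person
has but on how the trabecular (spongy) bone is organised.
Micro-computed tomography resolves individual trabeculae (at ~20 µm
voxels) and is the accepted in-vitro reference for quantifying that
architecture, but it cannot image patients. Clinical devices —
cone-beam CT (CBCT) and high-resolution peripheral quantitative CT
(HR-pQCT), at 75–400 µm voxels — can, at the cost of partial-volume
blurring, noise, and (for CBCT) uncalibrated intensity scales.

This package re-implements, as a tested pipeline, an in-vitro study
design built around that gap: segment trabecular bone from
clinical-resolution volumes with an automated region-growing scheme
that needs no intensity calibration; compute seven 3D histomorphometric
parameters; compute apparent stiffness and shear by voxel-based
micro-finite-element (micro-FE) homogenization of the fine-resolution
segmentation; and ask how well the clinical-resolution structure
parameters *predict* the micro-FE mechanics, via correlation, simple
and stepwise regression, with Bland–Altman analysis for scan–rescan
reproducibility. Because the original cadaver volumes are not publicly
available as images, the package ships a synthetic-specimen generator
so that every stage — and the full study design — can be exercised and
tested end to end in silico.

## Synthetic specimens

### Ground truth: thresholded Gaussian random fields

`generateGroundTruth()` draws white noise on the phantom grid, smooths
it with an anisotropic Gaussian kernel, and thresholds the smoothed
field by bisection until the bone fraction matches `targetBvtv` within
±0.005. Thresholded Gaussian random fields produce connected
plate-and-rod mixtures whose morphology statistics resemble trabecular
bone well enough to exercise skeleton-based metrics; they are not a
biomechanical growth model.

Two parameters control the morphology:

* `thicknessScaleMm` — the Gaussian correlation length (mm). For a
  field thresholded near BV/TV = 0.1 the mean chord length of the
  excursion set is close to twice the correlation length, so `Tb.Th ~
  2 * thicknessScaleMm`. The package's sphere-fitting thickness
  measures ~0.25 mm at `thicknessScaleMm = 0.15` (within the expected
  band: inscribed-sphere thickness is somewhat below mean chord
  length). The default 0.12 mm gives Tb.Th ≈ 0.24 mm.
* `anisotropy` — the ratio of the axis-3 correlation length to the
  transverse one. Values above 1 elongate structures along axis 3 and
  make the apparent stiffness tensor stiffest along that axis, which is
  how the principal ("E3") direction arises in real distal-radius
  specimens. Default 1.4.

The default geometry is deliberately scaled relative to the emulated
protocol: a 4.8 mm cube at 0.05 mm voxels (96³) in place of a ~12 mm
specimen at 0.02 mm (600³), preserving the ratio between the ~8 mm
analysis cube and the 5.3 mm FE cube (here 4.0 mm and 2.4 mm → 48³ FE
grids) and the ~3–4× clinical-to-fine voxel ratio. These problem sizes
keep a full 6–14-specimen study within minutes on one CPU while
retaining the regime that matters: trabeculae a few fine voxels and
roughly 1.5 clinical voxels thick.

### The scan simulator

`simulateScan()` models clinical re-imaging as: intensity assignment →
Gaussian point-spread blur → block-average resampling to an integer
multiple of the fine voxel (detector integration) → additive Gaussian
noise. Two modelling points deserve emphasis:

* **Intra-bone heterogeneity.** Real bone tissue varies in
  mineralization, and cone-beam devices add shading on an uncalibrated
  intensity scale. `boneHeterogeneitySd` (default 200 on a 1000
  bone–water contrast, correlation length 0.2 mm) injects spatially
  correlated intensity variation into the bone phase. This is not
  cosmetic: the region-growing schedule below anchors its threshold
  range to the intensity spread of the seed class, and with an
  unrealistically uniform bone phase that spread collapses to the
  noise level and the schedule can never reach over-segmentation.
* **Calibration to measured contrast-to-noise.** The default imaging
  specs (0.15 mm voxel / 0.20 mm PSF / noise 80, and 0.20 mm / 0.25 mm
  / 105 for the weaker device analog) were chosen once so the CNR
  measured by `cnr()` on pure-phase regions lands in the 6–10 range
  reported for the emulated devices, then frozen.

What the simulator does *not* model: beam hardening, scatter, ring and
motion artefacts, cortical shell, marrow inhomogeneity. Passing tests
on these phantoms therefore demonstrate algorithmic correctness and
the qualitative resolution-dependence of the measurements, not
device-level accuracy on real scans.

## Segmentation

### Automated region growing (ARG)

The ARG scheme targets uncalibrated gray-scale volumes. Its stages:

1. **Seeds** are selected from the attenuation-value distribution of
   the whole volume. By default the seed threshold is the
   between-class-variance (Otsu) split — so the seed set spans the
   whole bone intensity class, including the dim partial-volume fringe
   — accepted only when the class separation exceeds three noise
   standard deviations (noise estimated robustly from axial second
   differences). On near-unimodal histograms (very low bone fraction)
   the split would land inside the noise mode, so a background-outlier
   bound (histogram mode + 4 noise SDs) is used instead; either way
   the threshold is capped at the 99.5th percentile so seeds are never
   empty. A fixed-percentile rule (`seedPercentile`) remains available.
2. **Strictest homogeneity threshold** = the standard deviation of the
   seed intensities (floored to a small epsilon for degenerate,
   noise-free seeds).
3. **Threshold schedule**: 50 thresholds linearly spaced from the
   strictest to 1.6× it, both ends inclusive.
4. **Growth**: a voxel is admissible when its intensity does not fall
   more than the threshold below the seed mean; the mask is the union
   of admissible 6-connected components containing seeds. The
   criterion is one-sided because bone is the bright phase — a voxel
   brighter than the seed mean is never background. Using the *seed*
   mean as a fixed reference (rather than a running region mean) makes
   the 50-mask sequence monotone nested by construction and the result
   idempotent and order-independent. A running-mean variant is
   available in `regionGrow()`; on heavily blurred data its reference
   drifts down the partial-volume intensity continuum and the region
   jumps discontinuously from under-capture to background flooding,
   which is why it is not the default.
5. **Selection**: each mask is scored by the assessment function and
   the minimum wins (ties to the strictest iteration).

The assessment function is
`w1·log(WCV) − w2·log(G²)`, where WCV is the pooled within-class
variance of the mask partition and G² the mean squared intensity jump
across the mask boundary. The first term penalizes both
over-segmentation (the region swallows background and becomes
inhomogeneous) and under-segmentation (bone left outside inflates the
residual background variance); the second rejects masks whose boundary
runs through a single phase — in particular background floods, whose
boundaries carry only noise-level contrast. On a noise-free
two-intensity phantom the true mask scores −∞ and both ARG and the
histogram threshold recover it voxel-exactly. The exact functional
form of the assessment used in the original implementation is not
published; this form was chosen for those provable ordering properties
and is weight-configurable.

### Histogram threshold and CNR

`otsuSegment()` applies the classical between-class-variance threshold
and is used for the calibrated, high-CNR micro-CT analog. `cnr()`
implements |mean(bone ROI) − mean(background ROI)| / SD(background
ROI).

## Histomorphometry

Seven parameters, all computed in 3D on the binary mask:

* **BV/TV** — bone voxels over total voxels, an exact integer ratio.
* **Tb.Th / Tb.Sp** — mean sphere-fitting local thickness
  (Hildebrand–Rüegsegger) of the bone / background phase. The
  inscribed-sphere radius at a candidate center is its Euclidean
  distance to the complementary phase minus half a voxel, so an
  isolated voxel is one voxel thick; slabs of even voxel width are
  reported one voxel thin (the optimal sphere center falls between
  voxel centers), which keeps the measure within ±1 voxel of the
  analytic value. The exact Euclidean distance transform is computed
  by the separable lower-envelope algorithm; spheres contained in a
  neighbour's sphere are pruned before stamping.
* **Tb.Sc** — "spacing": the mean local thickness of the complement of
  the *mid-surface* skeleton, i.e. the distance between trabecular
  midlines/mid-planes. The mid-surface variant is used here because
  the complement of a curve skeleton of a plate does not measure the
  plate spacing.
* **Tb.N** — 1 / Tb.Sc (1/mm), trabeculae per unit length.
* **Tb.Nd / Tb.Tm** — junction clusters and free ends of the
  voxel-wide *curve* skeleton, per mm³ of the analysed volume.
  Junction voxels (≥3 skeleton neighbours) are merged 26-connectively
  so a thick crossing counts once; free ends touching the volume
  border are excluded (a trabecula cut by the field of view is not a
  free end).

Skeletonization is topology-preserving 6-directional thinning using
the simple-point characterization (a voxel is deletable iff removal
changes neither the object's 26-connectivity nor the background's
6-connectivity in its neighbourhood), with sequential re-verification
inside each directional pass. `preserve = "curves"` retains line ends;
`preserve = "surfaces"` retains width-1 plates. Outside the volume
counts as background, so volume-spanning structures thin from the
faces too; the border-terminus exclusion compensates downstream.

Free-end counts are known to be sensitive to the details of the
thinning algorithm; absolute Tb.Tm levels from different
implementations are not comparable, and the tests therefore pin them
only on constructed phantoms with unambiguous counts.

## Micro-FE homogenization

Every bone voxel of the (largest face-connected, boundary-anchored
component of the) mask becomes one linear isotropic 8-node hexahedral
element with tissue modulus 12 GPa and Poisson ratio 0.3. Apparent
elastic constants follow from six load cases under kinematic uniform
boundary conditions (KUBC): all nodes on the cube surface are
displaced by u = ε·x for each of the six canonical unit strains (three
normal, three engineering shear), and the interior is solved with a
sparse supernodal Cholesky factorization shared across the six
right-hand sides (relative residuals ~1e-14, far inside the 1e-8
contract). Element stiffness uses 2×2×2 Gauss quadrature, which is
exact for the trilinear cube element; the tests verify it against an
independent 4×4×4-point implementation.

The apparent stiffness column for each case is the volume-averaged
element stress — centroid stress times element volume, summed, divided
by the *total* cube volume (pores contribute zero). Averaging over
total rather than bone volume is the convention that makes the
homogeneous limit return the tissue constants exactly and the
two conventions differ by the factor BV/TV. C is
symmetrized ((C+Cᵀ)/2; the asymmetry, solver-level, is logged), and
engineering constants come from the compliance S = C⁻¹: E_i = 1/S_ii,
shear moduli from the shear diagonal. Young's moduli are reported
sorted so E3 is the maximum, implementing the convention that the
stiffest axis is the principal loading direction; Gmin is the smallest
of G12, G13, G23.

KUBC yields an upper-bound apparent stiffness, monotone under material
removal — the tests assert every diagonal entry of C shrinks when
voxels are deleted from nested masks. Apparent stiffness is invariant
to uniform voxel-size scaling (geometric similarity) and linear in the
tissue modulus; both are asserted.

Degenerate inputs: components not reaching the cube boundary cannot be
loaded by the boundary displacement and are removed in `buildModel()`
(the largest boundary-touching component is kept; the removed fraction
is reported). A specimen whose FE cube retains no load-bearing path
makes the system or the resulting C singular; `runStudy()` records
missing mechanics for such specimens rather than aborting.

## Statistical layer

* `pearsonCi()` — Pearson r with the Fisher-z normal-quantile CI (the
  same construction as `cor.test`, cross-checked in the tests).
* `simpleRegression()` — OLS with R², adjusted R², and the two-tailed
  t-test p of the slope.
* `stepwiseRegression()` — the probability-of-F stepwise variant:
  forward entry of the smallest-p candidate while p ≤ 0.05, backward
  removal at p ≥ 0.10 after each entry (the classical defaults of the
  statistics package used in the emulated study, exposed as
  parameters). Reported: the selection order, the single-predictor R²
  and the two-predictor adjusted R² (`adjustedR2()` implements
  1 − (1−R²)(n−1)/(n−k−1), which may be negative).
* `blandAltman()` — bias, 1.96·SD limits of agreement and a
  systematic-error flag (0 outside the t-CI of the bias).

## The in-silico study

`runStudy()` composes everything: per specimen, a ground truth, a fine
rescan segmented by histogram threshold (the micro-CT analog), two or
more degraded rescans segmented by ARG (the clinical analogs, one of
them repeated for reproducibility), the seven parameters per modality,
micro-FE on the FE cube of the fine segmentation, and a synthetic DXA
BMD column drawn uniformly in the 0.004–0.018 g/cm² range (deliberately
uncorrelated with structure — at this cube size areal BMD in the
emulated study carried no predictive information, and the generator
reproduces that null). Reports: correlations of every clinical
parameter with the fine reference, simple regressions of E3 and Gmin
on every parameter and modality, stepwise regressions (plus the DXA
row), descriptive statistics, and Bland–Altman agreement between the
repeated scans. Everything derives from one master seed and reruns are
byte-identical.

At the default scaled conditions the study reproduces the qualitative
findings of the emulated design: the clinical analogs overestimate
BV/TV relative to the fine reference (most strongly at low volume
fraction), apparent thickness grows with voxel size, BV/TV is a strong
significant predictor of E3 and Gmin (R² ≈ 0.9 for the fine
reference), the weaker clinical analog shows weaker correlations
throughout, and DXA predicts nothing. The real study's numeric tables
can be recomputed from its per-specimen raw-data sheet with
`reproduceStudyTables()`, which accepts a configurable column mapping
and an optional table of printed reference values
(`inst/extdata/reference_study_tables.csv`) for a two-decimal
side-by-side comparison.

## Numerical choices and limitations

* Bisection tolerance for phantom BV/TV: ±0.004 (contract ±0.005).
* Crops round the center half-down; all crops are whole-voxel.
* Assessment ties resolve to the strictest iteration; equal-size FE
  components tie-break to the lowest voxel index (warned).
* The thinning result depends on the fixed direction order
  (U/D/N/S/E/W cycles); it is deterministic and
  topology-preserving, but not rotation-invariant — axis-permutation
  tests allow 5% (15% for skeleton censuses).
* Local thickness carries a ±1 voxel discretization band; at clinical
  voxel sizes (structures ~1.5 voxels) this is a large relative
  uncertainty, mirroring the real partial-volume regime.
* The synthetic study's correlation *magnitudes* depend on the chosen
  degradation levels; only their ordering and signs are asserted in
  tests.
* Volumes are dense in-memory arrays; the intended scale is desk-sized
  (≤ ~200³ fine grids), not whole-bone clinical volumes.
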