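---
title: "Methods: contour agreement and voxel-wise correlation on multiparametric prostate MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contour agreement and voxel-wise correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DILagree)
```

## The problem

Dominant intraprostatic lesions are contoured on three mpMRI sequences with
different contrast mechanisms and different native resolutions: T2-weighted
anatomy (0.5 × 0.5 × 3.0 mm³), the ADC map fitted from diffusion-weighted
images (2.0 × 2.0 × 3.0 mm³), and the Ktrans permeability map from
dynamic contrast-enhanced imaging (1.5 × 1.5 × 3.0 mm³). After rigid
co-registration and resampling onto the T2W grid, the question is how well
the three contours agree — as volumes, and voxel by voxel — and whether
agreement varies with lesion zone or Gleason grade group. This package
implements that analysis as a tested pipeline, together with a synthetic
cohort generator that gives every stage a known ground truth.

## Data model and resampling

Grids are axis-aligned and anisotropic; `ImageGeometry` stores shape,
spacing (mm) and the physical position of the first voxel centre. Voxel
indices are 1-based and physical coordinates refer to voxel centres; all
distances are in mm. Oblique acquisitions (non-axis-aligned affines, off-
diagonal tolerance 1e-6) are rejected at the NIfTI boundary rather than
silently reoriented — the analysis is defined on co-registered, axis-
aligned grids, and rejecting avoids silent coordinate bugs.

`resampleToReference()` applies a *given* rigid transform (default
identity, appropriate for series that arrive co-registered) and trilinear
or nearest-neighbour interpolation at the transformed reference voxel
centres. Registration *estimation* is deliberately out of scope. Points
outside the moving volume receive a configurable fill value (default 0,
neutral for masks). Masks are resampled by interpolating the 0/1 field and
thresholding at 0.5, the standard majority rule. Volumes are stored in
NIfTI as float32 (the usual parametric-map precision), masks as uint8.

## Agreement metrics

Dice and Jaccard are computed from voxel counts on the shared grid. The
surface metrics are computed between *boundary point sets*: the centres of
true voxels with at least one false face-neighbour (6-connectivity, grid
edge counts as exposure). For each boundary point the Euclidean mm distance
to the nearest boundary point of the other contour is found by a compiled
sorted-sweep search; an all-pairs brute-force oracle in the test helpers
independently verifies these distances to 1e-9 mm.

Two conventions needed fixing, and both are documented choices rather than
inferences:

* **Pooling.** HD95 and MDA summarise the *pooled* bidirectional multiset
  (A→B and B→A distances together), not the maximum of directed
  percentiles. Pooling makes the two metrics mutually consistent — MDA is
  the mean and HD95 the 95th percentile of the same multiset — and the
  100th percentile of the pooled set coincides with the classical
  symmetric Hausdorff distance, which the tests assert.
* **Percentile method.** Linear interpolation between order statistics at
  position `q/100 · (n − 1)` (the common default, `quantile(type = 7)`),
  asserted bit-exactly in the tests (e.g. pooled {0×9, 10} at q = 95 gives
  5.5).

Empty-mask policy: both contours empty is an error (no boundary exists);
exactly one empty gives Dice = Jaccard = 0 with the distance metrics
undefined (NA). Note that HD95 ≥ MDA is *not* guaranteed in general — only
the 100th percentile dominates the mean — so the tests assert the latter.

## Voxel-wise correlation

The Boolean sum volume (BSV) is the union of the contours from all three
sequences, and it is used as the sampling region for *every* pair, so each
comparison uses the same, equal number of voxels. Within the BSV each map's
values become fractional ranks — average-tie ranks divided by n, lying in
(0, 1] — and Spearman's ρ is the Pearson correlation of the fractional
ranks. Average ties are the standard Spearman convention; the division by n
cancels in ρ and only affects the reported ranks. Spearman rather than
Pearson because only a monotone relationship between sequences is
plausible.

A map that is *constant* inside the BSV has no rank information; the
result is returned as a flagged undefined value (never a silent 0). This is
the mechanism that models Ktrans maps on which tumour and normal tissue are
indistinguishable, and flagged patients are excluded from Ktrans-involved
cohort averages rather than imputed.

## Cohort aggregation

Tables report mean ± sample SD (n − 1 denominator throughout; single-voxel
intensity contours report SD 0, single-patient strata report SD as
undefined) per stratum × pair × metric, plus a Total stratum. Zones are
stored four-way (AFS, CZ, PZ, TZ) but reported as AFS, Peripheral and
pooled Cent/Tran, mirroring the conventional presentation; Gleason grade
groups 4 and 5 are pooled at ingest and never reported separately. The
ADC-Ktrans pair is computed and reported as extended output alongside the
two T2W-anchored pairs. Composition percentages are computed over patients
with known labels, with unlabeled counts surfaced. The Total mean equals
the n-weighted mean of the stratum means by construction, which the tests
assert to 1e-12.

## The synthetic cohort generator

The generator emulates the *post-registration state* of a contouring
study; it is the package's own construction (a contouring study has no
generative model), with the minimum structure needed to make every stage
testable against known truth:

* **Lesions** are randomly oriented ellipsoids with mild axis anisotropy,
  volumes drawn from a lognormal with mean 2.14 mL and SD 2.1 mL (the
  reported cohort scale), placed near the grid centre and rejected if they
  cannot fit.
* **Contour variation** (between sequences and between observers) is a
  smooth random radial warp of the boundary about the lesion centroid,
  with RMS displacement equal to the configured scale in mm; scale 0 is
  the identity. The default per-sequence scales — 0.8 (T2W), 1.6 (ADC),
  2.6 (Ktrans) mm — were fixed once by the built-in Monte-Carlo
  calibration (`calibratePerturbation()`) so that the expected
  inter-sequence Dice sits at the agreement level such cohorts report
  (about 0.75 for T2W-ADC, 0.61 for T2W-Ktrans); closed forms for
  voxelised anisotropic shapes are intractable, so the calibration is
  empirical, seeded and reproducible. The second observer's contours add a
  further 2.8 mm RMS warp on top of the first observer's, calibrated the
  same way to the markedly lower agreement second contour sets show
  (Dice near 0.5 for T2W-ADC).
* **Parametric maps** are drawn voxel-wise from a Gaussian copula:
  latent correlated normals with Pearson parameter `r = 2 sin(π ρ_s / 6)`
  — the parameter whose implied population Spearman equals the target —
  transformed to the marginals (ADC: normal 990 ± 150 in 10⁻⁶ mm²/s
  truncated at 0; Ktrans: exponential with mean 4 min⁻¹; T2W: truncated
  normal in arbitrary units). Default pairwise Spearman targets are 0.20
  (T2W-ADC) and 0.13 (T2W-Ktrans), the cohort means this regime
  represents, and 0.10 for the unreported ADC-Ktrans pair (a package
  choice between the two printed values). Outside the BSV, background
  values are drawn independently from the same marginals.
* **ADC maps take a DWI round trip**: signals `S(b) = s0 exp(−b·ADC)` at
  b = 50, 400, 800 s/mm² receive additive Gaussian noise (default SD 1% of
  s0) and the ADC is re-fitted by least squares on centred log-signals.
  Non-positive noisy signals are excluded per voxel (fewer than two left
  → 0), negative slopes are clipped to 0, and both cases are flagged.
  Gaussian rather than Rician noise is a simplification, adequate at the
  simulated SNR and noted as a limitation.
* **Uninformative Ktrans** cases (default an exact 19/90 of the cohort)
  have their in-BSV Ktrans values replaced by independent background
  draws, making lesion and background statistically indistinguishable and
  the downstream correlation ≈ 0; the metadata flag drives the exclusion
  plumbing.
* **Metadata** are sampled from the zone weights 35.2/5.6/32.4/25.4 %
  (AFS/CZ/PZ/TZ, renormalised — the published percentages sum to 98.6,
  implying unlabeled cases, so percentages are always computed over
  labelled patients) and grade-group weights 30.3/39.4/17.2/13.1 %
  (the Results-table composition; the source abstract prints a slightly
  different one, and the package does not arbitrate — composition is
  whatever the input cohort contains).

Determinism: every draw derives from the master seed through per-patient
streams, so regeneration is byte-identical (including NIfTI payloads,
which are written uncompressed) and independent of evaluation order.

### A deliberate design choice: generation on the reference grid

Cohort volumes are generated directly on the common T2W reference grid
rather than on the native ADC/Ktrans grids followed by resampling. The
copula fields are independent across voxels, so they have no spatial
coherence; linearly interpolating such a field from a coarser grid would
average away most of its rank correlation, and the configured Spearman
targets could not survive a genuine coarse-grid round trip. Generating at
the reference resolution keeps the ground-truth correlation well-defined
at the voxels the analysis actually samples — which is also the state
co-registered study data arrive in. The resampling operator itself is
fully implemented and validated by its own tests (analytic midpoints,
identity exactness, no-overshoot bounds, volume preservation for masks),
and the native grid descriptors remain in the configuration for real-data
workflows. Emulating resolution transfer faithfully would require spatially
smooth random fields, which the generator does not model; this is a known
limitation.

### What passing tests do and do not show

The synthetic cohort demonstrates that the *pipeline* is correct: metrics
match independent oracles, configured correlations and volumes are
recovered, exclusions propagate, and runs are reproducible. It does not
demonstrate anything about real contouring behaviour — real inter-sequence
disagreement is not a smooth radial warp, real maps have spatial texture
and artefacts, and real uninformative Ktrans arises from physiology, not
resampling of the lesion values. Cohort numbers produced from the
generator's defaults characterise the simulated regime, not patients.

## Numerical choices, at a glance

| Choice | Value | Where |
|---|---|---|
| Boundary connectivity | 6-neighbour faces, grid edge = exposed | `extractBoundary()` |
| HD/MDA pooling | pooled bidirectional multiset | `hausdorffPercentile()`, `meanDistanceToAgreement()` |
| Percentile | linear interpolation, type-7 | `hausdorffPercentile()` |
| Mask resampling threshold | 0.5 | `resampleMask()` |
| Out-of-support fill | 0 (configurable) | `resampleToReference()` |
| Axis-alignment tolerance | 1e-6 on off-diagonal affine terms | `readNiftiVolume()` |
| Tie handling | average ranks | `fractionalRanks()` |
| SD denominator | n − 1 everywhere | cohort module |
| Spearman→Pearson copula map | `2 sin(π ρ_s / 6)` | `generateCorrelatedPair()` |
| Degenerate inputs | classed errors / flagged NA, never silent 0 | throughout |

## Problem sizes used by the test-suite

The tests exercise oracle equivalence on 200 random mask pairs within
12 × 12 × 6 grids, copula recovery at 2 000 BSV voxels across five targets,
the noisy ADC fit on 10⁴ voxels, full-pipeline byte-level determinism on a
20-patient cohort at the default 72 × 72 × 16 reference grid, and the
exclusion plumbing on a 90-patient cohort — sizes chosen so the whole suite
characterises every contract while remaining comfortable to run routinely.

## Known limitations

Only axis-aligned geometries; no registration estimation; Gaussian (not
Rician) DWI noise; no Tofts modelling of the DCE series (Ktrans maps are
taken or simulated as given); voxels are treated as exchangeable in the
correlation (no spatial autocorrelation correction), matching the analysis
being reproduced; and the generator's reference-grid design above.
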