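# DILagree

Agreement analysis of dominant intraprostatic lesion (DIL) contours on
multiparametric prostate MRI.

When a radiotherapy boost is planned to the dominant intraprostatic lesion,
the target volume depends on which MR sequence the lesion was contoured on:
T2-weighted anatomy, the apparent diffusion coefficient (ADC) map from
diffusion-weighted imaging, or the Ktrans permeability map from
dynamic contrast-enhanced imaging. DILagree quantifies how well contours
drawn on these sequences agree with one another — volumetrically and
voxel-by-voxel — and aggregates the results over a cohort, stratified by
lesion zone and Gleason grade group. It is aimed at medical-physics and
radiation-oncology researchers evaluating mpMRI-based target delineation.

## What it computes

For a pair of binary contours A and B rasterised on a common axis-aligned
grid (anisotropic voxels, all distances in physical mm):

* **Dice coefficient** `2|A ∩ B| / (|A| + |B|)` and **Jaccard index**
  `|A ∩ B| / |A ∪ B|` (so `Dice = 2J/(1+J)` row by row);
* **95% Hausdorff distance (HD95)** and **mean distance to agreement
  (MDA)**: the 95th percentile and the mean of the pooled bidirectional
  multiset of boundary nearest-neighbour distances, where the boundary is
  the set of face-exposed true voxels (6-connectivity) and distances are
  Euclidean in mm;
* **voxel-wise Spearman correlation**: a Boolean sum volume (BSV) — the
  union of the contours from all three sequences — fixes a common voxel
  sample; each map's values inside the BSV are converted to fractional
  ranks (average ties, divided by n) and correlated, so every sequence pair
  is compared over the same voxels.

Cohort tables report mean ± SD per sequence pair and metric, by lesion zone
(AFS, peripheral, pooled central/transition) and by Gleason grade group
(1, 2, 3, 4+5), with patients whose Ktrans map is uninformative excluded
from Ktrans-involved pairs only. A synthetic cohort generator (ellipsoidal
lesions, smooth boundary perturbation, Gaussian-copula parametric maps, DWI
synthesis with monoexponential ADC re-fitting) provides known ground truth
for every stage; see the methods vignette (`vignettes/methods.Rmd`).

## Worked example

```r
library(DILagree)

g <- ImageGeometry(c(72, 72, 16), c(0.5, 0.5, 3.0))   # T2W-like grid
set.seed(42)
base <- generateBaseLesion(g, volumeMl = 2.0)
t2w  <- perturbLesion(base, 0.8, label = "T2W/obs1")  # contour variation
adc  <- perturbLesion(base, 1.6, label = "ADC/obs1")
t2w
#> BinaryMask [T2W/obs1]: 2290 / 82944 voxels set (1.718 mL)
#> ImageGeometry: 72 x 72 x 16 voxels, spacing (0.5, 0.5, 3) mm, origin (0, 0, 0) mm

pairMetrics(t2w, adc)
#> $dice    0.719
#> $jaccard 0.562
#> $hd95    3.81      # mm
#> $mda     1.20      # mm

bsv  <- booleanSumVolume(list(t2w, adc))
pair <- generateCorrelatedPair(bsv, targetRhoS = 0.20)
spearmanInBSV(pair[[1]], pair[[2]], bsv)
#> $rho 0.203  $n 4044  $defined TRUE
```

The two contours are independent smooth perturbations of the same lesion:
they overlap well (Dice 0.72) but their boundaries disagree by up to ~4 mm
at the 95th percentile, mostly along the coarse 3 mm slice direction. The
copula-generated map pair recovers its configured rank correlation (0.203
vs a target of 0.20 over the 4044 BSV voxels).

The full pipeline runs over a cohort directory of NIfTI files:

```r
cfg <- syntheticConfig(nPatients = 90, seed = 1)
runSimulate(cfg, "cohort/")
runMetrics("cohort/", "metrics.csv")
runVoxelwise("cohort/", "voxelwise.csv")
runCohort("metrics.csv", "voxelwise.csv", "cohort/metadata.csv", "tables/")
```

A thin command-line wrapper with the same stages is installed at
`inst/scripts/dil_pipeline.R`.

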