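# petdyntex

Dual-time-point FDG-PET tumor texture analysis for R.

## The problem

Tumor FDG uptake keeps rising for hours after injection, so a lesion
imaged at the standard ~60-minute uptake time and again ~3 hours after
injection shows different SUV metrics — and, because the usual
fixed-fraction segmentation threshold tracks the growing SUVmax, a
different segmented volume and different spatial texture. Anyone
comparing heterogeneity biomarkers across scans, timepoints or centers
needs the whole measurement chain — SUV computation, delineation, volume
metrics, texture matrices, paired statistics — implemented with explicit,
testable conventions. petdyntex provides that chain for researchers
working with paired PET acquisitions of the same lesion, plus a seeded
phantom generator so every claim can be exercised without patient data.

## What it computes

* **SUV** with explicit decay correction,
  `SUV = SV·RS·W / ((RTD·DF)·exp(−ln2·Et/HF))`, per slice, so raw data
  from both acquisitions live on one decay scale.
* **Segmentation**: manual 3D box → voxels ≥ 40% of box SUVmax
  (inclusive), enclosed cold cores accounted as necrosis (never
  hole-filled), hottest 26-connected component kept.
* **Metrics**: SUVmax, SUVmean, SUVpeak (3×3×3-voxel cube), MTV (cm³),
  TLG = SUVmean × MTV.
* **18 textural features** on a 16-level discretized VOI:
  co-occurrence family (ENT, HOM, CON, DIS, UNI) over the 26
  neighbours of each voxel; run-length family (SRE, LRE, LGRE, HGRE,
  SRLGE, SRHGE, LRLGE, LRHGE, GLNU, RLNU, RPC) over the 13 3D
  directions; gradient energies SE = ‖∇u‖/‖u‖ and TE = ‖∇u‖/SUVmax on
  the raw SUV field.
* **Paired cohort statistics**: paired T or Wilcoxon signed-rank
  selected by Shapiro–Wilk on the differences, statistics signed so
  negative = PET-1 lower; Spearman associations of texture with
  MTV/TLG with |r| > 0.75 flagged strong; MTV ≤ 10 / > 10 cm³
  stratification.
* **Synthetic paired phantoms**: 128×128 matrix, 5.47×5.47×3.27 mm
  voxels, ellipsoidal lesions ≥ 2 cm with a correlated Gaussian texture
  field, optional necrotic core, and delayed-acquisition dynamics (gain
  × profile sharpening: SUV up ≈ 18%, threshold MTV down ≈ 7%).

See `vignette("dual-time-point-texture")` for the models, conventions
and design decisions.

## Worked example

```r
library(petdyntex)

ph    <- make_phantom(phantom_spec(seed = 42))   # paired PET-1 / PET-2
mask1 <- segment_lesion(ph$pet1, ph$truth$box)
mask1
#> Tumor mask: 86 voxels at threshold 3.674 (40% of box SUVmax)
#>   enclosed necrotic voxels: 0

f1 <- extract_features(ph$pet1, mask1)
f2 <- extract_features(ph$pet2, segment_lesion(ph$pet2, ph$truth$box))
round(rbind(PET1 = f1, PET2 = f2)[, c("suv_max", "mtv_cm3", "ENT", "GLNU", "SE")], 3)
#>      suv_max mtv_cm3   ENT   GLNU    SE
#> PET1   9.185   8.414 5.282 89.754 0.093
#> PET2  10.401   7.534 5.060 81.849 0.094
```

The delayed scan is hotter (SUVmax 9.19 → 10.40) while the 40% threshold
volume shrinks (MTV 8.41 → 7.53 cm³) — the characteristic
dual-time-point signature. At cohort level:

```r
cc  <- make_cohort(12, seed = 7,
                   spec_sampler = default_spec_sampler(grid_shape = c(48, 48, 24)))
rep <- compare_timepoints(cc$cohort)
rep[rep$variable %in% c("suv_max", "mtv_cm3", "tlg"), ]
#>  variable             PET-1             PET-2     test    T/Z        p
#>   suv_max  10.765 +/- 2.890  12.390 +/- 3.295 paired-T -13.53 0.0000 *
#>   mtv_cm3  12.923 +/- 8.947  12.206 +/- 8.405 wilcoxon   2.93 0.0039 *
#>       tlg 87.253 +/- 63.888 95.093 +/- 70.049 paired-T  -4.24 0.0014 *
```

Negative statistics mean the PET-1 value was lower: SUVmax rises and MTV
falls at the delayed timepoint. The volume–texture confounding the
literature warns about is directly visible:

```r
p1 <- cc$cohort[cc$cohort$timepoint == "PET1", ]
spearman(p1$GLNU, p1$mtv_cm3)
#> Spearman r = 0.993 (p = 1.302e-10, n = 12) [strong]
```

GLNU is almost a proxy for tumor volume — texture differences must be
read with MTV in view.

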