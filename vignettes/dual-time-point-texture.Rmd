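---
title: "Dual-time-point PET texture analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-time-point PET texture analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

petdyntex quantifies intratumoral heterogeneity on paired FDG-PET
acquisitions of the same lesion — a standard scan about 60 minutes after
injection and a delayed scan about 3 hours after injection. Because tumor
FDG uptake keeps rising for hours while the fixed-fraction segmentation
threshold tracks the growing SUVmax, both the SUV metrics and the texture
of the segmented volume are *dynamic* quantities; the package measures
that dynamics and the statistics built on it. This vignette explains the
models, the conventions, and the choices made where the design was open.

## SUV computation

Stored pixel values are converted to body-weight SUV (g/ml) with an
explicit decay correction referencing the time elapsed since injection:

$$\mathrm{SUV} = \frac{SV \cdot RS \cdot W}
{(RTD \cdot DF)\, e^{-\ln 2 \cdot Et/HF}}$$

with stored value $SV$, rescale slope $RS$, patient weight $W$ (g),
injected dose $RTD$ (Bq), half-life $HF$ (s; 6588 s for ¹⁸F), decay factor
$DF$, and per-slice elapsed time $Et$ (s). Correcting each slice to its
own acquisition time makes raw data from the standard and the delayed
acquisition directly comparable on one decay scale. Two conventions
matter:

* **Per-slice $Et$** — when only a scan-level time is known it is applied
  uniformly (a note is emitted).
* **$DF$ defaults to 1.** Many scanner exports pre-apply decay
  correction; passing the vendor's factor *and* a nonzero $Et$ would
  double-correct. The package treats $DF$ as given metadata and leaves
  avoiding double correction to the caller, because exports differ too
  much to guess safely.

Weight in grams with dose in Bq makes the quotient dimensionally g/ml,
the usual body-weight SUV.

## Segmentation

Delineation is deliberately simple and reproducible: a manual 3D box
around the lesion, then every voxel in the box with SUV **equal to or
above 40%** of the box SUVmax. Conventions, each used consistently
throughout the package:

* The comparison is inclusive (≥), so a voxel exactly at the threshold
  belongs to the tumor.
* The SUVmax reference is the maximum inside the user box, not the whole
  image — the box is the manual localization step.
* Connectivity is the 26-neighborhood everywhere (components, necrosis
  flood fill, co-occurrence pairs).
* The two timepoints are segmented independently, each against its own
  SUVmax; no registration between them is attempted.
* Central sub-threshold regions completely enclosed by tumor (reachable
  from no box face) are treated as necrosis: they stay excluded — no hole
  filling — and their voxel count is recorded in the mask provenance.
* With multifocal uptake, the 26-connected component containing the
  hottest voxel is kept (ties: larger component, then lowest linear
  index). A `hottest_only = FALSE` flag disables the selection, since
  whether the threshold region was reduced to one component before
  computing metrics is a choice users may want to control.

These rules give the threshold mask three useful invariants that the test
suite checks: raising the fraction never grows the mask, multiplying all
SUVs by a positive constant never changes it, and re-thresholding a
masked field is idempotent.

## SUV and volume metrics

For a volume with voxel spacing $(d_x, d_y, d_z)$ in mm:

* **SUVmax, SUVmean** — maximum and arithmetic mean over the VOI.
* **SUVpeak** — maximum over VOI-centred 3×3×3-voxel cubes of the cube's
  mean. By default the cube uses every image voxel it covers, truncated
  only at the image boundary; this matches the common "physical
  neighborhood" definition of SUVpeak. A `masked_only` flag restricts
  cube means to VOI voxels for users who prefer the stricter reading.
* **MTV** $=$ voxel count × $d_x d_y d_z / 1000$ (cm³) — the scale of the
  usual ≤ 10 / > 10 cm³ stratification.
* **TLG** $=$ SUVmean × MTV.

Note SUVmean ≤ SUVmax and SUVpeak ≤ SUVmax always hold, but SUVmean ≤
SUVpeak does not (the peak cube may average cold neighborhood voxels).

## Texture features

Texture is computed on 16 gray-level classes. Masked SUVs are binned with
equal width between the VOI minimum and maximum:
$\ell = \min(N, \lfloor N (s - \min)/(\max - \min)\rfloor + 1)$, with a
constant VOI mapping to level 1 (lowest bin for a degenerate range).
Binning is per-lesion (relative) because each lesion is discretized
against its own dynamic range; fixed bounds can be supplied via the
`bounds` argument when cross-lesion comparability of absolute SUV matters.

**Co-occurrence matrix (local texture).** Every ordered pair of
26-adjacent in-mask voxels increments $CM(\ell_a, \ell_b)$; one aggregated
matrix over all 13 distance-1 directions and their opposites, symmetric
by construction, normalized to probabilities. Five features: entropy
($-\sum p \ln p$, natural log, $0 \ln 0 = 0$), homogeneity
($\sum p/(1+(i-j)^2)$), contrast ($\sum p (i-j)^2$), dissimilarity
($\sum p |i-j|$), uniformity ($\sum p^2$).

**Run-length matrix (regional texture).** For each of the 13 directions,
maximal runs of collinear same-level in-mask voxels; out-of-mask voxels
terminate runs (runs live inside the tumor; no bridging). Every masked
voxel belongs to exactly one run per direction, giving the conservation
law $\sum_{ij} RLM(i,j)\, j = 13\,|\mathrm{mask}|$ that the tests assert
on every input. Eleven features (SRE, LRE, LGRE, HGRE, SRLGE, SRHGE,
LRLGE, LRHGE, GLNU, RLNU, RPC) follow the standard weighted-sum
definitions; RPC's denominator is the conserved quantity above.

**Energies (gradient-based).** On the *raw* SUV field, not the
discretized one: specific energy
$SE = \left(\int |\nabla u|^2\, dV\right)^{1/2} /
\left(\int |u|^2\, dV\right)^{1/2}$ (intensive, scale-free in $u$) and
total energy $TE = \left(\int |\nabla u|^2\, dV\right)^{1/2} /
\max_{g \in u}$, normalized by the VOI SUVmax (extensive — it grows with
the domain). The gradient uses central differences in physical mm,
falling back to a one-sided difference where one axis neighbor leaves the
mask and contributing zero where both do; integrals are voxel sums times
the voxel volume in mm³. The continuum formulas do not prescribe a
discretization, so this scheme is an implementation choice, chosen
because it is exact for linear fields in the interior and degrades
gracefully at the irregular mask boundary.

**Anisotropic voxels.** The matrix families treat all 13 directions
equally even though diagonal neighbors are physically farther apart (no
distance weighting is defined for them); the energies *do* use physical
spacing. This asymmetry is deliberate and documented rather than hidden.

## Cohort statistics

Paired PET-1 vs PET-2 comparison per variable: Shapiro–Wilk on the paired
differences at the 0.05 level selects the paired $T$ test (normal) or the
Wilcoxon signed-rank test (otherwise) — an explicit rule, since "use the
non-parametric test when needed" is not reproducible. The reported
statistic is signed so that **negative means PET-1 was lower**; the
Wilcoxon normal deviate is computed with midranks and tie correction and
signed by the same convention regardless of library internals. All-zero
differences are a degenerate case: the statistic is 0, p is 1, and a
warning names the variable. Multiplicity correction (Holm or Bonferroni)
is available but off by default, since which correction "when needed"
means is a user decision.

Associations use Spearman rank correlation (midranks for ties, p from the
large-sample $t$ approximation), with $|r| > 0.75$ flagged as strong, and
an MTV stratification at 10 cm³ (boundary value inclusive in the small
group, at a configurable timepoint).

## The phantom generator

Real dual-time-point breast-cancer PET data of the kind this pipeline
targets is not publicly deposited, so every end-to-end claim is exercised
on synthetic phantoms with known ground truth:

* 128 × 128 acquisition matrix, voxel size 5.47 × 5.47 × 3.27 mm
  (defaults), ellipsoidal lesions of ≥ 20 mm diameter on a flat
  background (default background 1 SUV, lesion peak 8 SUV above it —
  SUVmax near 9, matching typical locally advanced breast tumors);
* a multiplicative texture field: a Gaussian random field smoothed to a
  correlation length of 8 mm. Correlated texture, not voxel-iid noise,
  because cellular-scale heterogeneity is blurred to roughly this scale
  by PET's limited spatial resolution;
* an optional spherical necrotic core at sub-threshold uptake;
* additive Gaussian acquisition noise (default SD 0.1 SUV);
* PET-2 = lesion gain × sharpened profile: uptake multiplied by
  `pet2_gain` (default 1.18) and the radial profile raised to
  `pet2_contrast` (default 1.06). The two knobs reproduce the two
  characteristic delayed-acquisition effects — SUV metrics rise by
  roughly 18% and the fixed-fraction threshold volume shrinks by roughly
  7% — with the gain chosen to match the typical reported SUVmax rise and
  the contrast exponent derived in closed form from the threshold
  geometry to land the volume change near −7%. These are interpretable
  defaults, not ground truth; both are tunable fields of the phantom spec.

All randomness flows through one explicit integer seed; generation is
byte-reproducible, and the caller's RNG stream is left untouched. The
cohort sampler draws lesion diameters uniformly on 20–50 mm (spanning
both MTV strata), peak uptake on 5–14 SUV and texture amplitude on
0.1–0.3.

**What the phantoms do not model:** scanner physics (point-spread
function, Poisson sinogram noise, reconstruction artifacts), respiratory
motion, anatomical background structure, or uptake-time variability
between patients. Passing tests therefore demonstrate correctness of the
measurement chain and the statistical machinery under controlled
dynamics — not clinical performance on patient images.

### A non-obvious interaction worth knowing

Increasing the smooth texture amplitude raises entropy and lowers
uniformity/homogeneity monotonically, but it does *not* raise contrast,
dissimilarity or the specific energy. Two mechanisms: per-lesion relative
binning renormalizes the widened SUV range (CM features are invariant to
affine rescaling of the VOI), and a field correlated at 8 mm adds little
voxel-to-voxel difference at 5.47 mm sampling, while its contribution to
the field norm lowers $SE$. Voxel-scale roughness is what CON, DIS and SE
respond to — the suite demonstrates this by spatially shuffling a smooth
field (identical level histogram, higher CON/DIS/SE, lower HOM). This is
a property of the measurement definitions, not a bug, and it is why
volume effects and binning choices must be controlled before reading
texture differences biologically.

## Numerical conventions and degenerate inputs

* Threshold comparison inclusive; empty thresholds and empty masks are
  errors, not silent zeros (an MTV of 0 is a contract violation).
* Constant VOI → all voxels level 1; CM then has all mass at (1,1)
  (ENT 0, HOM 1, UNI 1), energies are 0.
* CM requires at least one adjacent in-mask pair; texture is undefined
  (an error) on fully scattered masks.
* $0 \ln 0 = 0$ in the entropy; CM must be normalized within 1e-8 before
  feature evaluation.
* Spearman on a constant vector is undefined: NA with a warning, never a
  fabricated 0.
* Feature tables round-trip through CSV at full double precision
  (`%.17g`).

## Problem sizes used by the test suite

The oracle tests compare the matrix builders against brute-force
enumeration on 200 random masks up to 6×6×6 — exact equality, not
tolerance. The cohort-level properties run on scaled-down grids chosen so
the full suite stays comfortably inside a desktop run: effect-direction
recovery uses 100 cohorts of 56 patients on 48×48×24 grids, and the
type-I study uses 1000 cohorts of 16 patients with 20–30 mm lesions on
32×32×16 grids, both at the standard voxel spacing — the grid extent only
pads analysis-irrelevant background, while voxel size, lesion physical
size and dynamics are the defaults. The per-seed effect-direction check
(`SUVmax` up, MTV down on every seed) runs on the full default
128×128×32 geometry because MTV changes of a few percent sit at the
single-voxel quantization limit and are sensitive to the noise stream.

## Known limitations

* DICOM series input is not implemented; volumes enter as NIfTI (plus a
  JSON metadata sidecar) or as in-memory arrays with per-slice elapsed
  times.
* No partial-volume correction, no background-normalized uptake ratios,
  no histogram (non-spatial) heterogeneity features, and no gradient or
  adaptive segmentation — the fixed 40% threshold is the method under
  study.
* The Wilcoxon p value uses the exact distribution where the data allow
  and the normal approximation otherwise (the reported Z is always the
  tie-corrected normal deviate), so p and statistic can disagree slightly
  in magnitude for tiny samples.
* Texture features on VOIs smaller than a few cm³ are dominated by
  quantization; the generator's 20 mm minimum lesion diameter reflects
  the smallest size for which the pipeline's outputs are meaningful at
  PET resolution.
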