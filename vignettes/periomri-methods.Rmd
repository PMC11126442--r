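---
title: "Quantifying periodontal bone-marrow edema from longitudinal MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying periodontal bone-marrow edema from longitudinal MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periomri)
```

## The measurement problem

Periodontitis is an inflammatory disease of the tooth-supporting tissues.
Its clinical staging rests on probing: pocket depth (PPD, integer mm) and
bleeding on probing (BOP) at up to six sites per tooth. On fat-suppressed
MRI (STIR-type sequences), inflammatory infiltration of the alveolar
bone marrow appears as hyperintense *bone-marrow edema*, which offers an
imaging biomarker of bone involvement: its linear apical–coronal extent at
a probing site (edema depth, ED, mm) is the radiographic analogue of PPD,
and its volume per quadrant (mm³) summarizes the burden of disease.

`periomri` implements the full longitudinal measurement chain for paired
(baseline, follow-up) scans:

1. **Rigid co-registration** of the follow-up volumes into the baseline
   frame, so that volumes of interest and linear measurements refer to
   identical anatomical positions at both visits.
2. **Voxelwise edema classification**: a voxel inside the quadrant ROI and
   the osseous compartment is called edema when its signal exceeds the mean
   of an explicitly edema-free reference-marrow region by strictly more
   than *k* reference standard deviations (*k* = 2 by default).
3. **Change maps** between the two visits — reduction (baseline only), new
   (follow-up only), stable (both) — with volumetry as voxel count × voxel
   volume (0.65³ mm³ at the default isotropic 0.65 mm spacing).
4. **Edema depth** at each of the six probing sites per molar, and the
   per-tooth maximum used for statistical comparison.
5. **Site-level statistics**: median [IQR] summaries, paired Wilcoxon
   signed-rank, Mann–Whitney, and Pearson chi-square (with Yates correction
   on 2×2 tables), assembled into the standard clinical and imaging
   summary tables.

Because no patient data ship with the package, every stage is exercised on
synthetic inputs with exact ground truth: an imaging phantom and a clinical
site simulator.

## The classification model and its assumptions

Let $\mu$ and $\sigma$ be the mean and SD of signal in the reference marrow
mask of a given scan. Voxel $v$ in ROI $\cap$ bone is classified as edema
iff

$$ I(v) > \mu + k\,\sigma, \qquad k = 2 \text{ (default)}, $$

with a *strict* inequality (ties at exactly $k\sigma$ are excluded). Because
$\mu$ and $\sigma$ are re-estimated per scan, the rule is invariant to
global scanner gain differences between visits — an implicit per-scan
standardization ($z > k$). The reference mask must be edema-free by
construction; the package does not attempt to find it.

Two estimators are provided for $(\mu, \sigma)$: the sample moments
(default) and a robust pair (median, 1.4826 × MAD, SD-consistent under
normality) for reference regions that may contain residual bright voxels.
A degenerate reference ($\sigma = 0$, e.g. on a synthetic noiseless image)
is flagged and classification refuses to run; for noiseless phantoms the
generating values can be supplied via `manual_reference_stats()`.

Under pure Gaussian noise the rule has an analytic false-positive rate: a
fraction $1 - \Phi(k)$ of edema-free ROI voxels exceeds the threshold
(2.275% at $k = 2$). This is a *property of the rule, not a bug*, and the
package treats it as a first-class quantity: `experiment_null_fraction()`
measures it on a lesion-free phantom and the acceptance suite checks
agreement with the normal tail to within three binomial standard errors.
Consequences for volumetry are discussed below.

### Subtraction ambiguity

A subtraction-based protocol can be read two ways: difference two
per-timepoint classification masks, or threshold the subtraction image
itself. The package defaults to **mask differencing** (`change_maps()`),
because the $k$ SD criterion is defined against marrow signal, not signal
change; `subtraction_change_maps()` implements the other reading
(thresholding the per-scan-standardized difference at $k$ SD of the
difference noise, $\sqrt{2}$ times the single-scan SD) for comparison. On
the default route `reduction + stable` equals the baseline edema volume and
`new + stable` the follow-up volume, exactly, for all inputs.

### Minimum-cluster filter

`classify_edema(min_cluster_mm3 = ...)` optionally removes 6-connected
components smaller than a given volume. It **defaults to off**, matching a
protocol that specifies no cluster filtering. The parameter-recovery
experiments (below) enable it, and the reason is quantitative: with a
quadrant ROI of $N$ voxels, the analytic noise floor contributes
$0.02275\,N\,\times$ voxel-volume of false-positive edema per visit —
~60 mm³ for a 9,000-voxel ROI — which would swamp a 100 mm³ lesion. The
floor consists almost entirely of isolated voxels and tiny clusters, so a
20 mm³ (≈73-voxel) filter removes it while leaving lesions of ≥100 mm³
untouched. Real-protocol users who keep the filter off should interpret
absolute volumes relative to that floor; the change maps inherit the same
consideration.

## Edema depth

ED at a tooth site is measured by casting a ray from the alveolar crest
point along the apical direction, sampling every quarter voxel
(0.1625 mm by default) with nearest-voxel lookup in the classification
mask, and taking the **length of the longest contiguous run** of
edema-positive samples. The longest-run reading (rather than
crest-to-deepest-voxel distance) reflects a linear extent of edematous
marrow; quarter-voxel stepping bounds the digitization error well below
one voxel. Depths are reported raw and rounded to integer millimetres
(`rounding = "nearest_mm"`); site *records* use the rounded value, matching
probing granularity, and the per-tooth summary is the maximum over its
sites (`tooth_max_depth()`).

## Rigid registration

`estimate_rigid()` is a deterministic multi-resolution intensity method:

* pyramid of block-mean downsampled volumes (shrink factors 4/2/1 by
  default), each level Gaussian-smoothed (σ = 0.8 voxel);
* mean-squared-difference metric for same-contrast pairs (default), or a
  correlation metric (`"ncc"`) for cross-contrast registration;
* six parameters (three Euler angles about the fixed-volume centre, three
  translations in mm) refined per level by Nelder–Mead descent, seeded at
  the coarsest level by an exhaustive translation grid search (±6 mm in
  1.5 mm steps).

Two numerical choices deserve a note. First, the **per-level smoothing is
load-bearing**: on sharp images the MSD metric has a local dimple at exact
lattice alignment (interpolation is exact there and blurs under any
sub-voxel shift), which can trap a direct-search optimizer at its starting
point; smoothing removes the dimple. Second, the **grid search** makes the
capture range for translations explicit and deterministic. There is no
stochastic sampling anywhere, so registration results are bit-for-bit
reproducible for fixed inputs and options.

Conventions: a `rigid_transform` acts on world points as
$p \mapsto R(p - c) + c + t$; `resample_volume(vol, T)` pushes the image
forward through $T$; `estimate_rigid(fixed, moving)` returns the $T$ for
which `resample_volume(moving, T)` aligns with `fixed`. World coordinates
are RAS-like with the affine `diag(spacing)` and the origin at the volume
corner (voxel centre $i$ at $i \times$ spacing, 0-based). Masks are
resampled with nearest-neighbour, intensities trilinearly.

Equivalence with any particular external registration tool is not claimed;
the contract is recovery of known misalignments, which
`experiment_registration_recovery()` verifies (≤5°, ≤5 mm recovered with
target registration error below one voxel on noiseless phantoms).

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds a deliberately schematic jaw: a cortical box
shell (2 voxels thick, hypointense on the black-bone companion) around a
marrow slab split into four quadrant ROIs, molar probing sites along the
ridge with apical rays, ellipsoidal edema lesions blended into the marrow
with a raised-cosine edge over one voxel (so partial-volume behaviour
exists and depth/volume recovery is not unrealistically exact), a known
rigid inter-visit misalignment, and Gaussian (default) or Rician noise.
Key defaults, chosen once as the study conditions:

| parameter | default | meaning |
|---|---|---|
| `voxel_size_mm` | 0.65 | isotropic spacing of the emulated protocol |
| `marrow_mean` / `marrow_sd` | 100 / 10 | reference level and the SD unit for contrast and threshold (SNR 10) |
| `noise_sd` | `marrow_sd` | actual noise amplitude; 0 gives noiseless phantoms with well-defined contrast |
| lesion contrast | user, > 2 SD to be detectable | amplitude in `marrow_sd` units |
| `noise_model` | `"gaussian"` | makes the analytic null of the SD rule exact; `"rician"` available |

Scanner intensity units and SNR of any specific system are unknown free
parameters; the defaults are round numbers at a clinically plausible SNR,
not a calibration to specific hardware. The phantom's ground truth is
exact by construction: lesion masks are voxel-centre digitizations, truth
volumes are mask count × voxel volume (conservation is asserted, not
approximated), per-site truth depths are analytic ray–ellipsoid chord
lengths, and the truth transform is recorded. What the phantom does *not*
emulate: anatomically faithful jaw geometry, pulse-sequence physics,
susceptibility or motion artifacts, bias fields, through-plane anisotropy.
Passing recovery tests therefore demonstrates correctness of the
*measurement chain*, not robustness to every real-world confound.

## The clinical simulator

`generate_site_table()` draws paired site records (PPD, BOP, ED) with the
marginal structure of a treated periodontitis cohort. Sites fall into four
baseline strata — PPD ≤ 3 mm without BOP, PPD ≤ 3 mm with BOP, PPD 4–5 mm,
PPD ≥ 6 mm — with default probabilities (0.342, 0.178, 0.33, 0.15) at
baseline and (0.4275, 0.1425, 0.31, 0.12) after treatment (the merged-band
marginals are 52/33/15% and 57/31/12%). PPD within a stratum follows a
configurable integer distribution whose defaults reproduce the stratum
medians (3 [1, 3], 3 [3], 4 [4, 5], 6 [6, 7] mm); BOP probabilities per
stratum give ~45% bleeding sites at baseline falling to under 30%. Edema
presence at baseline is stratum-dependent (12/25/40/85%, marginal ≈34.5%);
a baseline-edema site persists with probability 0.55 and an edema-free site
converts with probability 0.085 (follow-up marginal ≈24.5%), which makes
the pre/post ED comparison genuinely paired. ED given edema follows
per-stratum integer distributions with baseline medians near 2 mm shifting
down after treatment. Timepoints draw their stratum independently — sites
migrate between strata under treatment, which is what produces lower
within-stratum follow-up PPD medians — and this is the main simplification:
no site-level PPD transition kernel, no within-patient or within-tooth
correlation. Statistics that lean on site clustering would need a richer
generator; the package's tables treat sites as the unit of analysis, as the
tabulation convention it reproduces does.

## Statistical conventions

* **Median [IQR]**: linear-interpolation percentiles (R `quantile`
  type 7); the convention is recorded in every table.
* **Paired Wilcoxon**: zero differences dropped (classical treatment —
  documented because software defaults differ), mid-ranks for ties,
  *exact* two-tailed p by exhaustive enumeration over sign assignments for
  up to 12 non-zero pairs (exact even under ties), otherwise the
  tie-corrected normal approximation with continuity correction. All zero
  differences ⇒ degenerate, p = 1.
* **Mann–Whitney**: exact by enumeration when both groups have ≤8
  observations, otherwise tie-corrected normal approximation with
  continuity correction.
* **Chi-square**: Pearson statistic; Yates continuity correction applied
  exactly when the table is 2×2 (`"auto"`), as in the tabulation convention
  reproduced here (no correction on the 2×3 category-band table).
* **Category comparisons between visits** use the *unpaired* chi-square on
  per-visit counts even though sites are paired — replicating the reporting
  convention of the clinical literature this package mirrors. A
  marginal-homogeneity test (`marginal_homogeneity()`, Stuart–Maxwell;
  McNemar for two categories) is provided as the statistically paired
  alternative but nothing calls it by default.
* Percentages are rounded half-up to integers for table rendering, always
  with explicit denominators; significance is two-tailed at 0.05 with no
  multiplicity adjustment.

The exact small-sample paths are implemented in-package because the base-R
tests fall back to approximations under ties; base R serves as the
independent cross-check on tie-free inputs, and exhaustive enumeration
oracles (written separately in the test suite) cover the tied cases.

## Validation experiments and problem sizes

The `experiment_*()` family runs the package's standard recovery studies;
the test suite and `scripts/acceptance.R` call exactly these functions.
Problem sizes were chosen as the smallest that make each property
identifiable:

* **Null fraction**: one 80×80×56 phantom (~1.6×10⁵ marrow voxels), so the
  binomial SE of the classified fraction is ~4×10⁻⁴ against an expected
  0.02275.
* **Volume recovery**: 20 phantoms (48×48×64), single lesions of
  100–1000 mm³ at +6 SD, SNR 10, 20 mm³ cluster filter. Recovery error is
  dominated by the deterministic digitization/edge-blend bias (largest for
  small lesions), not by noise.
* **Change recovery**: one shrinking lesion (radius 6 → 4.5 mm); reduction
  compared against the analytic shell $\tfrac{4}{3}\pi(r_0^3 - r_1^3)$.
* **Depth recovery**: extents 1–8 mm planted under a probing site;
  noiseless runs use analytic reference statistics (digitization-limited),
  SNR-10 runs use the full estimation path with a 5 mm³ filter (a 20 mm³
  filter would delete the smallest legitimate lesions, whose total volume
  is ~8 mm³).
* **Registration recovery**: three noiseless misalignments up to 5°/5 mm,
  TRE over marrow-ROI corners.
* **Simulator calibration**: table-builder percentages averaged over 30
  replicate cohorts of exactly 922 sites. One such cohort carries ~1.6
  percentage points of binomial SE per band, so a single draw cannot
  discriminate a 3-point calibration error from noise; the replicate mean
  at the same cohort size can.
* **Wilcoxon power**: 200 replicate cohorts; rejection rate of the paired
  test on baseline-edema sites at the 0.05 level.

## Known limitations

* The registration capture range for rotations is what multi-resolution
  descent provides (tested to 5°); gross rotational misalignment would need
  a rotational grid search or landmark initialization.
* Absolute volumetry at the default settings (no cluster filter) includes
  the analytic false-positive floor; quadrant-level volumes should be read
  relative to it.
* The schematic phantom cannot certify robustness to real-MRI confounds
  (bias fields, artifacts, anisotropic voxels, imperfect manual masks).
* The simulator reproduces marginal cohort structure, not within-patient
  correlation; mixed-effects extensions are out of scope.
* Oblique NIfTI orientations are not supported; volumes are assumed
  axis-aligned with a corner origin.
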