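# periomri

Quantifying bone-marrow edema of the alveolar ridge from longitudinal
dental MRI.

## The problem

Periodontitis is staged clinically by probing: pocket depth (PPD, mm) and
bleeding on probing (BOP) at six sites per tooth. On fat-suppressed
(STIR-type) MRI, inflammatory infiltration of the jaw's bone marrow appears
as hyperintense **bone-marrow edema**, giving an imaging biomarker of bone
involvement that can be followed through treatment. `periomri` implements
the full measurement chain for paired baseline/follow-up scans, for imaging
scientists and biostatisticians who want a tested, reproducible pipeline:

- **Rigid co-registration** of follow-up volumes into the baseline frame
  (deterministic multi-resolution intensity registration);
- **Edema classification**: voxel `v` in the quadrant ROI ∩ osseous
  compartment is edema iff `I(v) > μ + k·σ` with `(μ, σ)` the mean/SD of an
  edema-free reference-marrow region of the *same scan* and `k = 2` by
  default (strict inequality);
- **Change maps** — reduction (`e₀ ∧ ¬e₁`), new (`¬e₀ ∧ e₁`), stable
  (`e₀ ∧ e₁`) — with volumes = voxel count × 0.65³ mm³;
- **Edema depth (ED)**: the longest contiguous run of edema along the
  apical–coronal ray of each probing site, in mm;
- **Site-level statistics**: median [IQR], paired Wilcoxon signed-rank
  (exact under ties at small n), Mann–Whitney, Pearson chi-square with
  Yates correction for 2×2 tables, and builders for the standard clinical
  (PPD/BOP) and imaging (ED) summary tables;
- A **ground-truthed phantom generator** and a **clinical site simulator**,
  so every stage is testable without patient data.

Tabular results are tibbles throughout, with `tidy()`, `glance()` and
`autoplot()` methods; volumes are NIfTI-1 in and out.

## Worked example

Simulate a two-visit phantom with a lesion that shrinks from radius 4 mm to
3 mm (analytic shell 155 mm³) under a known 2° / ~2 mm misalignment, then
run the measurement chain:

```r
library(periomri)

cfg0 <- phantom_config(grid_shape = c(48, 48, 64), seed = 1)
site <- generate_phantom(cfg0)$sites[8, ]           # tooth 37, buccal_mid
ctr  <- c(site$crest_x, site$crest_y, 27.3 - 6)     # 6 mm below the crest

cfg <- phantom_config(
  grid_shape = c(48, 48, 64),
  lesions_t0 = list(lesion(ctr, 4, contrast_sd = 6)),
  lesions_t1 = list(lesion(ctr, 3, contrast_sd = 6)),
  true_transform = rigid_transform(angles = c(0, 0, 2 * pi / 180),
                                   translation = c(1.5, -1, 0.8),
                                   center = c(15.3, 15.3, 15.3)),
  seed = 1
)
ph <- generate_phantom(cfg)
ph$truth$volumes
#>   timepoint volume_mm3
#> 1 t0              268.       # 4/3·π·4³ = 268.1
#> 2 t1              113.

reg <- estimate_rigid(ph$stir_t0, ph$stir_t1)
glance(reg)
#>   metric metric_value converged levels iterations rot_deg trans_mm
#> 1 msd            17.2 TRUE      4/2/1        1473    2.07     1.97

stir_t1_reg <- resample_volume(ph$stir_t1, reg$transform)
ref0 <- reference_stats(ph$stir_t0, ph$marrow_ref_mask)
ref0
#> <reference_stats> mean 100, sd 10.01 (moment, n = 53601)

e0 <- classify_edema(ph$stir_t0,  ph$marrow_mask, ph$bone_mask, ref0,
                     min_cluster_mm3 = 20, roi_id = "all", timepoint = "t0")
e1 <- classify_edema(stir_t1_reg, ph$marrow_mask, ph$bone_mask,
                     reference_stats(stir_t1_reg, ph$marrow_ref_mask),
                     min_cluster_mm3 = 20, roi_id = "all", timepoint = "t1")
tidy(change_maps(e0, e1))
#>   quadrant reduction_mm3 new_mm3 stable_mm3 voxel_size_mm
#> 1 all               139.       0       148.          0.65

measure_site_depths(e0, ph$sites) |> dplyr::filter(ed_mm > 0)
#>   tooth_id position         ed_mm ed_mm_rounded
#> 1 37       buccal_anterior   7.8              8
#> 2 37       buccal_mid        8.29             8
#> 3 37       buccal_posterior  7.8              8
```

The recovered transform matches the planted misalignment (2.07° vs 2°,
1.97 mm vs 1.95 mm); the measured reduction (139 mm³) sits near the
analytic shell (155 mm³, the difference being edge digitization plus
interpolation of the registered follow-up); and the site under which the
lesion was planted reads an 8 mm edema depth — the planted sphere's
diameter — with its neighbours slightly less, as their rays cut shorter
chords.

Clinical tables come from site records (simulated here; any CSV with the
same columns works):

```r
rec <- generate_site_table(clinical_sim_config(n_patients = 35, seed = 1))
build_table2(rec)   # PPD median [IQR] per stratum, category counts, BOP row
build_table3(rec)   # affected-site counts and ED median [IQR] per stratum
chi_square(rbind(c(591, 379, 170), c(631, 347, 132)))
#> <perio_test> Pearson chi-square
#>   statistic = 7.10252, p = 0.02869, n = 2250 (normal approximation)
```

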