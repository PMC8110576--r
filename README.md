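# tomohet

Spatial heterogeneity of liver stiffness from multifrequency MR
elastography (MRE), as a tested end-to-end pipeline on synthetic data.

## The problem

Cholestatic liver disease such as primary sclerosing cholangitis (PSC)
lays down fibrosis patchily — segment by segment — while viral hepatitis
stiffens the liver diffusely. Mean liver stiffness, the standard
elastography readout, is blind to this difference. The candidate
biomarker implemented here is the **coefficient of variation** of the
shear-wave-speed (SWS) map within a liver volume of interest (VOI):

    CV = 100 * SD(SWS) / mean(SWS)   [%]

computed voxelwise per subject. The package provides everything needed to
study this biomarker without patient data:

* **`phantom_spec()` / `make_phantom()` / `synthesize_wavefield()`** —
  viscoelastic liver phantoms in two disease archetypes (heterogeneous
  focal vs homogeneous diffuse stiffening, with vessel-like low-speed
  tubes) on the standard acquisition geometry (9 slices, 100 × 78 matrix,
  3 × 3 × 5 mm voxels, 35–60 Hz, 8 time offsets), and geometric-optics
  synthesis of the multifrequency complex wave fields (eikonal travel
  times, attenuation `alpha = k tan(phi/2)`).
* **`invert_subject()`** — tomoelastography-style reconstruction:
  temporal harmonic extraction, 12-direction k-space filtering,
  per-direction phase-gradient wave numbers, and amplitude-weighted
  compounding of 12 × 3 × 6 = 216 images per slice into SWS maps, plus
  Helmholtz-based fluidity (phi) maps.
* **`build_voi()` / `summarize_map()` / `stage_fibrosis()`** — VOI with
  the 1 m/s lower SWS threshold, mean/SD/CV statistics, and fibrosis
  staging by the published cutoffs F1 ≥ 1.52, F2 ≥ 1.55, F3 ≥ 1.67,
  F4 ≥ 1.72 m/s.
* **`simulate_cohort()` / `build_cohort_table()`** — two-group cohorts
  with clinical covariates, Welch t-tests, Pearson correlations,
  Mann–Whitney AUC with DeLong 95% CI, and the APRI and Mayo-risk-score
  calculators.
* **`run_end_to_end()` / `render_report()`** — seeded, bit-reproducible
  pipeline runs with NIfTI map output, CSV tables and a markdown report.

## Worked example

```r
library(tomohet)

# a heterogeneous-archetype subject with ground-truth parenchymal CV 21%
spec <- phantom_spec(archetype = "heterogeneous_focal",
                     target_cv_percent = 21, background_sws_mps = 1.70,
                     seed = 101)
gt <- make_phantom(spec)
wf <- synthesize_wavefield(gt, spec)   # 8 sources x 6 frequencies
e  <- invert_subject(wf)               # 216 compounded images per slice
subject_stats(e, gt$liver_mask)
#>   sws_mean    sws_sd   sws_cv  phi_mean    phi_sd  phi_cv stage voi_cm3
#> 1 1.693848 0.3283033 19.38209 0.4466811 0.1651219 36.9664     3 745.515
```

The reconstruction recovers the imposed
ground truth: a VOI mean near the generating 1.70 m/s, a recovered CV
within two percentage points of the generating 21%, and the corresponding
fibrosis stage under the published cutoffs. Staging the two
representative printed cases:

```r
stage_label(stage_fibrosis(c(1.56, 1.69)))
#> [1] "F2" "F3"
```

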