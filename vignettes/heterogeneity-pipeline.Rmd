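---
title: "Quantifying spatial heterogeneity of liver stiffness with multifrequency MRE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial heterogeneity of liver stiffness with multifrequency MRE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomohet)
```

## The scientific problem

Chronic cholestatic liver disease (the archetype being primary sclerosing
cholangitis, PSC) produces fibrosis with a patchy, segmental spatial
distribution, while chronic viral hepatitis stiffens the liver much more
uniformly. Global liver stiffness, the standard elastography biomarker,
cannot distinguish these patterns. `tomohet` implements a complete,
simulation-backed pipeline for the candidate biomarker that can: the
**coefficient of variation (CV)** of the shear-wave-speed map within a
liver volume of interest,

$$\mathrm{CV} = 100 \cdot \frac{\mathrm{SD}(\mathrm{SWS})}{\overline{\mathrm{SWS}}}\ [\%],$$

computed per subject over the voxels of the VOI. Because no patient data
are distributed with this kind of study, the package ships a first-class
synthetic-data module that generates the full acquisition: ground-truth
viscoelastic maps, multifrequency complex wave fields, and clinical
covariates, so that every stage of the chain — inversion, VOI statistics,
staging, cohort comparison — can be validated against a known truth.

## The phantom: what it emulates and what it does not

`phantom_spec()` mirrors a typical multifrequency abdominal MRE protocol:
9 axial slices on a 100 × 78 matrix with 3 × 3 × 5 mm voxels, drive
frequencies 35–60 Hz in 5 Hz steps, and 8 time offsets over one vibration
period. The phantom body is a torso-like ellipse containing an ellipsoidal
liver (~0.8 L) and thin vessel-like tubes fixed at 0.5 m/s, below the
1 m/s VOI threshold, so that the vessel-exclusion mechanism of the VOI is
exercised.

Two archetypes set the spatial structure of the true SWS field:

* `heterogeneous_focal` — one or two confluent regions of elevated
  stiffness with radii of roughly 5–7 cm, emulating segmental/lobar
  involvement. The scale matters: the drive wavelengths are 45–80 mm, and
  heterogeneity much finer than a wavelength is physically invisible to
  any wave-based reconstruction. Sub-wavelength lesions would make the
  recovery tests meaningless, so the generator places lesions at the
  anatomical (Couinaud-segment to lobe) scale that a radiologist would
  actually describe, which is also the scale the inversion can resolve.
* `homogeneous_diffuse` — a smooth Gaussian random field with a
  multi-centimetre correlation length, emulating diffuse stiffening with
  mild large-scale variation.

When `target_cv_percent` is set, the texture is standardised over the
parenchyma (liver minus vessels) and the field is built as
$\mathrm{SWS}(x) = \mu\,(1 + \tfrac{cv}{100} B_{std}(x))$, so the
parenchymal mean is exactly `background_sws_mps` and the parenchymal CV is
exactly the target. Anchoring the *mean* (rather than a background level)
matches how cohort tables report group values: as means over subject VOI
means. Fluidity is uniform in the parenchyma; vessels are given a high,
fluid-like phase angle.

What the phantom deliberately does not model: MR acquisition physics
(motion encoding, coil sensitivities, parallel imaging), anatomical organ
shape, respiratory motion, through-plane wave propagation, and
inflammation/portal-pressure confounders of stiffness. Passing tests on
these phantoms therefore demonstrate correctness of the *processing
chain*, not clinical performance on real livers.

## Wave synthesis

Each drive frequency receives `n_sources` (default 8) plane wavefronts
entering the body from evenly spaced directions. Waves propagate in the
geometric-optics limit:

* the phase is $2\pi f\,T(x)$, where the travel time $T$ solves the
  eikonal equation $|\nabla T| = 1/c(x)$ — so the local wave-number
  magnitude equals $2\pi f / c(x)$ by construction, which is precisely the
  quantity the phase-gradient inversion estimates;
* the log-amplitude is the ray-path integral of the attenuation
  $\alpha = k \tan(\varphi/2)$, the plane-wave consequence of the fluidity
  $\varphi$ being the phase angle of the complex shear modulus
  $G^* = \rho\omega^2/k^{*2}$.

The eikonal equation is solved per slice by a monotone Godunov upwind
relaxation with the exact plane-wave ramp imposed outside the body (where
the medium is uniform); the attenuation integral is transported along the
computed rays by an upwind transport relaxation. On uniform media both
solvers reproduce the analytic plane wave to machine precision, which is
what makes the closed-form oracles in the test suite exact. A
straight-ray approximation was evaluated first and rejected: it violates
$|\nabla \text{phase}| = k(x)$ in and behind inclusions, i.e. it breaks
the very identity the inversion relies on, and systematically flattened
recovered heterogeneity.

Time offsets sample $u(x,t) = \mathrm{Re}[U(x)e^{-i2\pi f t}]$ at 8
uniform phases; Gaussian noise (SD = `noise_sigma` × mean amplitude,
default 5%) is added inside the body. Displacement is exactly zero outside
the body, as in masked in vivo data.

## Inversion

`invert_subject()` composes four operators, all exported individually:

1. **Harmonic extraction** — temporal DFT over the offsets; the
   fundamental bin returns $A e^{i\theta}$ for a sampled
   $A\cos(2\pi f t + \theta)$.
2. **Directional filtering** — each slice's 2-D spectrum is split into 12
   angular sectors with raised-cosine windows that sum to unity over
   angle, times a radial band-pass $[2\pi f/c_{max},\ k_{Nyq}]$. With 3
   components and 6 frequencies this yields the canonical 216 compounded
   images per slice.
3. **Phase-gradient speed** — the local wave number of each directional
   field is the magnitude of the in-plane phase gradient, computed from
   wrapped one-voxel phase differences `Arg(U(x+h) conj(U(x)))` averaged
   forward/backward. This is algebraically the gradient of the unwrapped
   phase wherever the per-voxel phase step is below π, and it is *exact*
   on discrete plane waves — no unwrapping pass and no finite-difference
   sinc bias. SWS = $2\pi f/|\nabla\phi|$.
4. **Amplitude-weighted compounding** — per-voxel weighted mean of the
   216 per-direction speeds, weights equal to the filtered amplitudes.
   Estimates are discarded where the amplitude falls below 5% of the
   maximum over the 12 directional fields of that (component, frequency,
   slice), or where the implied speed exceeds `c_max` (out of the filter
   band). Voxels with no valid contribution are set to 0 and flagged —
   they subsequently fall below the 1 m/s VOI threshold, which is exactly
   the published mechanism for excluding regions of insufficient wave
   excitation.

Fluidity is estimated by algebraic Helmholtz inversion,
$\varphi = \arg(-\rho\omega^2 u / \nabla^2 u)$, aggregated over components
and frequencies by magnitude-weighted circular averaging and clipped to
$[0, \pi/2)$. The harmonic field is low-pass smoothed (Gaussian, 1 voxel)
before the Laplacian; plane waves are eigenfunctions of that smoothing, so
the closed-form oracle is unaffected while the noise amplification of the
second derivative is strongly reduced.

### Numerical parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_directions` | 12 | — | canonical compounding structure (12 × 3 × 6 = 216) |
| `c_max` | 4.0 | m/s | radial low-cut; 3.0 was evaluated and clips the k-space support of stiff (≥ 2.5 m/s) regions that occur in cirrhotic livers, biasing CV down; 4.0 retains them while still suppressing compression-wave leakage |
| `amplitude_floor` | 0.05 | fraction | published "insufficient excitation" mechanism; referenced to the cross-direction maximum so that genuinely unexcited voxels are dropped rather than kept with junk estimates |
| `voi_threshold_mps` | 1.0 | m/s | published lower SWS threshold, inclusive |
| staging cutoffs | 1.52 / 1.55 / 1.67 / 1.72 | m/s | published F1–F4 cutoffs, inclusive (≥) |
| density ρ | 1000 | kg/m³ | standard soft-tissue assumption |
| SD denominator | N − 1 | — | sample SD; immaterial at ~10⁴ voxels but fixed for reproducibility |

## Statistics

Group comparisons use Welch's two-sided t-test by default (group sizes and
variances differ between the two disease groups; the pooled-variance
Student variant is available via `ttest = "student"` for sensitivity
checks). Group-level CV entries are **means of per-subject CVs** — never
the ratio of group-level SD and mean summaries, which is a different and
non-equivalent quantity. Correlations are Pearson's r. Diagnostic
performance of CV as a group classifier is the Mann–Whitney AUC (ties
counted ½) with a DeLong 95% confidence interval; the AUC is computed from
ranks and verified in the tests against exhaustive pair counting and
against an independent reference implementation. APRI and the revised Mayo
risk score are implemented with their published formulas and category
bands; band edges follow the printed half-open convention (APRI 0.5, 1.0
and 1.5 open the next band, 2.0 closes the significant-fibrosis band; a
Mayo score of exactly 2 is intermediate). No multiple-testing correction
is applied, matching the single-threshold α = 0.05 design.

The cohort simulator draws subject-level mechanical parameters (mean SWS,
CV, fluidity) and clinical covariates from group distributions whose
defaults are the published group means and interindividual SDs (SWS
1.70 ± 0.28 vs 1.84 ± 0.38 m/s; CV 21 ± 5 vs 18 ± 3%; φ 0.48 ± 0.10 vs
0.50 ± 0.13 rad; ages 41 ± 14 vs 50 ± 14). Quantities without published
group summaries (platelets, albumin, AST upper limit of normal) use
conventional clinical values: AST ULN 40 U/L, albumin 4.0 ± 0.5 g/dL,
platelets drawn lognormally with the viral-hepatitis group lower (170 vs
220 ×10⁹/L) to reflect its greater cirrhotic fraction. Right-skewed labs
(AST, bilirubin, platelets) are lognormal with moments matched to the
requested mean and SD.

## Design choices that were genuinely open

* **Per-slice 2-D processing.** Elastograms are compounded per slice and
  the 3 × 3 × 5 mm voxels are strongly anisotropic; in-plane angular
  sectoring is well conditioned, through-plane sectoring is not.
* **Wave model.** Geometric-optics synthesis (eikonal + transport) rather
  than full elastodynamic FEM: it is exactly self-consistent with the
  phase-gradient estimator, provides closed-form oracles, and runs in
  seconds per subject. The price is the absence of diffraction,
  reflection, and mode conversion; recovered-vs-true comparisons should be
  read with that in mind.
* **Texture scales as free parameters.** No quantitative lesion geometry
  is published for PSC; lesion size, count and correlation lengths are
  exposed in the generator, with defaults at the anatomically and
  physically sensible (resolvable) scale discussed above.
* **VOI volume.** The reported VOI volume is the post-threshold volume
  (voxels actually analysed), not the contoured-liver volume.
* **Stage labels** are integers 0–4 internally; `stage_label()` maps to
  "F0"–"F4" only at the reporting layer.

## Problem sizes used in the tests

Unit tests run on reduced grids (e.g. 3 × 40 × 50) where the property
under test is size-independent. The parameter-recovery study runs the full
9 × 78 × 100 acquisition grid with 5 phantoms per archetype at the two
group-mean CV levels (21% and 18%), 5% noise and fixed seeds, and checks
group-mean recovery within 2 percentage points. The null-calibration study
uses 100 simulated cohorts of 20 + 26 subjects drawn from identical group
distributions (statistics path only) and checks AUC ≈ 0.5 and a rejection
rate near α. Determinism is checked by running the full pipeline twice at
a reduced size and comparing CSVs byte for byte.

## Known limitations

* Recovered CV is a *measured* quantity: it contains a few percentage
  points of reconstruction variance and loses a comparable amount of true
  contrast to resolution limits. At the study's heterogeneity levels these
  effects roughly balance; at much finer texture scales the chain would
  systematically under-read heterogeneity, as any wave-based method must.
* The fluidity estimator is unbiased on clean damped plane waves but reads
  low by ~0.05 rad under 5% displacement noise and in strongly interfering
  fields; the per-subject fluidity *CV* is correspondingly noisy. This is
  consistent with fluidity-based heterogeneity measures showing no group
  separation in clinical cohorts of this design.
* Clinical covariates are drawn independently of the mechanical
  parameters within each group, so correlation analyses on simulated
  cohorts test plumbing, not biology.
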