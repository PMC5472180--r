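# bbbflow

Tissue-specific blood-brain barrier (BBB) leakage analysis for slow
dynamic contrast-enhanced (DCE) MRI in cerebral small vessel disease.

## The problem

In small vessel disease the BBB does not fail catastrophically — it leaks
subtly, diffusely, and preferentially in and around white matter
hyperintensities (WMH). At these low permeabilities, pharmacokinetic
parameter fitting is fragile (it leans on capillary-density assumptions
that do not hold across an ageing, diseased brain), so a robust
alternative is to quantify leakage directly as the **slope of
post-contrast signal enhancement over a long acquisition** (~24 min),
tissue by tissue, and model those slopes against clinical covariates.
`bbbflow` implements that whole analysis chain for imaging researchers:

- **T1 mapping** from two pre-contrast spoiled-gradient-echo (SPGR)
  acquisitions at flip angles of 2° and 12°:
  `S = M0 sin(a) (1 - E1) / (1 - E1 cos(a))`, `E1 = exp(-TR/T1)`,
  inverted per voxel by the exact two-point variable-flip-angle solution.
- **Leakage quantification**: relative enhancement
  `e(t) = (S(t) - S_pre)/S_pre` averaged per tissue compartment, then an
  ordinary least-squares slope `de/dt` over the late window (the bolus
  frame is excluded), reported on the conventional ×10³ per-minute scale.
  The sagittal sinus provides the intravascular (blood-pool) reference.
- **Spatial contour analysis**: normal-appearing white matter (NAWM) is
  divided into 10 concentric rings, each two voxels (~2 mm) wide,
  expanding from the WMH edge by dilation restricted to the NAWM mask;
  WMH are split into intense / less-intense halves by FLAIR intensity.
- **Diffusion metrics**: log-linear tensor fit, `MD = trace(D)/3` and
  `FA = sqrt(3/2) ||lambda - mean(lambda)|| / ||lambda||` per contour.
- **Inference**: linear mixed models of per-patient, per-tissue slopes
  with a random patient intercept — per-tissue effects of age, WMH burden
  (Fazekas score) and stroke subtype, adjusted for blood pressure,
  hypertension, smoking, pre-contrast T1 and intravascular signal; a
  linear leakage gradient across the contours; and linear models of
  1-year cognition (ACE-R) on standardized WMH leakage.

Because no public dataset carries this protocol, the package ships a
**synthetic cohort generator**: a Patlak forward model
`C(t) = Ktrans * integral(Cp) + vp * Cp(t)` with a declining blood-pool
curve, SPGR signal conversion, Rician noise, diffusion-tensor phantoms,
clinical covariates and cognition — all with known ground truth, so every
stage is validated end-to-end by parameter recovery.

## Worked example

Simulate a 120-patient cohort at the default acquisition (20 frames over
24 min, flips 2°/12°), measure slopes, and fit the per-tissue WMH-burden
model:

```r
library(bbbflow)

cfg    <- cohort_config(n_patients = 120, seed = 42)
cohort <- generate_cohort(cfg)
slopes <- simulate_cohort_slopes(cohort)

fit_leakage_model(slopes, focus = "fazekas")
#> Coefficients (beta x 10^3, Wald 95% CI):
#>     term       stratum estimate ci95_low ci95_high  p_value
#>  fazekas          nawm   0.0112  -0.0476    0.0700 7.09e-01
#>  fazekas           dgm   0.0557  -0.0023    0.1137 5.98e-02
#>  fazekas           csf   0.1992   0.1410    0.2574 1.92e-11
#>  fazekas           wmh   0.1100   0.0438    0.1761 1.12e-03
#>  fazekas index_infarct   0.0212  -0.0369    0.0792 4.75e-01
#>  fazekas   old_infarct   0.0264  -0.0533    0.1061 5.16e-01
```

Each row is the change in enhancement slope (×10³ per minute) per
Fazekas point in that tissue: in this draw, leakage rises significantly
with WMH burden in CSF and in the WMH themselves, as the generating
truth (CSF 0.205, WMH 0.104, NAWM 0.024, all ×10⁻³) prescribes.

The spatial gradient across the NAWM contours, positive meaning more
leakage closer to the WMH edge:

```r
fit_contour_gradient(slopes)
#> Coefficients (beta x 10^3, Wald 95% CI):
#>               term       stratum estimate ci95_low ci95_high  p_value
#>  contour_proximity nawm_contours   0.0108  0.00552    0.0161 6.22e-05
```

And the cognition change model — ACE-R at 1 year on standardized WMH
leakage, adjusting for baseline ACE-R, NART, Fazekas, age and
hypertension (truth −1.89 points per SD of leakage):

```r
fit_cognition_model(slopes)
#>    term  estimate  ci95_low ci95_high      p_value
#>  leak_z     -2.37     -3.29     -1.45  4.6e-07
```

The voxel-level route does the same through images: `generate_anatomy()`
→ `paint_contour_labels()` → `simulate_dce()` / `simulate_dwi()` →
`fit_t10_vfa()` → `quantify_patient()` → `fit_tensor()`, orchestrated by
`run_pipeline()`, which writes NIfTI maps, tidy CSV tables and a
checksummed manifest. A thin CLI wraps these functions
(`inst/cli/bbbflow.R`, subcommands `simulate | t1map | contours |
quantify | dti | fit | run`).

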