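---
title: "Methods: slope-based BBB leakage analysis and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slope-based BBB leakage analysis and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bbbflow)
```

# The measurement model

## Why slopes, not permeability constants

At the low permeabilities typical of cerebral small vessel disease,
pharmacokinetic fits (Patlak, Tofts) are dominated by assumptions about
capillary surface area and blood volume that vary with age and disease.
`bbbflow` therefore treats the **late-window slope of relative signal
enhancement** as the leakage metric: per tissue compartment,

$$ e(t) = \frac{S(t) - S_{pre}}{S_{pre}}, \qquad
   \text{leakage} = \widehat{\mathrm{d}e/\mathrm{d}t}
   \ \ (\times 10^3\ \text{min}^{-1}), $$

an ordinary least-squares slope over all dynamic frames after the first
(the first frame carries the bolus first pass and is excluded by
default; the window is configurable via `fit_window_min`). Enhancement
is normalised by the pre-contrast baseline so that coil gain and proton
density cancel; a raw-difference mode exists for diagnostics. The slope
is computed on the tissue-mean curve (mean-then-slope), which is the
natural estimator for compartment-level inference; a voxelwise
slope-then-mean mode would be preferred for mapping, and is not the
default here.

The Patlak model
$$ C(t) = K^{trans} \int_0^t C_p(\tau)\,\mathrm{d}\tau + v_p C_p(t) $$
appears **only in the simulator and in test oracles**, never as the
measurement: the pipeline deliberately reports slopes, not
$K^{trans}$.

## T1 mapping

Two pre-contrast spoiled-gradient-echo volumes (flip angles 2° and 12°,
the protocol defaults) determine T1 exactly through the linearised
variable-flip-angle system: regressing $S/\sin\alpha$ on $S/\tan\alpha$
gives slope $E_1 = e^{-TR/T_1}$. With exactly two flip angles the
system is determined, so nonlinear least squares would add nothing.
Voxels whose slope falls outside $(0,1)$, or whose T1 falls outside
[50, 10000] ms (a bracket generously containing brain tissue and CSF),
are flagged invalid and reported — never silently zeroed. No B1
inhomogeneity correction is modelled. TR has no default: it must come
from the acquisition.

A note on degeneracy: *equal* signals at 2° and 12° are not impossible —
at TR ≈ 8 ms they correspond to a valid T1 near 2.2 s, where the two
flips straddle the Ernst angle. Genuinely impossible patterns (low-flip
signal far above high-flip) push $E_1$ past 1 and are flagged.

## Contours

NAWM is subdivided into `n_contours = 10` rings of `width_voxels = 2`
(~2 mm on a 1 mm grid) expanding from the WMH edge, by iterated
morphological dilation **restricted to the NAWM mask at each step**
(6-connectivity by default, 26 available). The restriction means rings
grow through white matter only and cannot cross CSF or grey matter and
re-enter; distance is therefore an in-mask (geodesic) chamfer distance,
measured in voxels. Whether contours should be restricted this way is a
modelling choice — contours are defined here as subdivisions of NAWM, so
restriction is the coherent reading. On anisotropic grids a
physical-distance mode via an exact Euclidean distance transform
(`distance_transform()`) is available; note it is unrestricted.
Contours are global to the WMH set, not per-lesion.

The WMH intense / less-intense split thresholds FLAIR intensity at a
configurable quantile (default the median) within the WMH mask; ties go
to less-intense, so a uniform lesion is all less-intense. This is a
single-sequence simplification of what is, in practice, a
multi-sequence visual judgement.

## Inference

The slope table (one row per patient × compartment) feeds linear mixed
models with a **random patient intercept** (`lme4`). Following the
one-interaction-family-at-a-time convention, each focus covariate — age
per 5-year increment, Fazekas score per point, stroke subtype coded so
negative means lower in lacunar — gets its own model with a per-tissue
interaction, the other focus covariates and the adjustment set
(hypertension, mean arterial pressure, pulse pressure, smoking,
pre-contrast tissue T1 in seconds, sagittal-sinus level) entering as
main effects. Inference is Wald with a normal approximation;
degrees-of-freedom corrections are out of scope; p-values are
unadjusted for multiplicity across tissues (stated, deliberate). Fits
are complete-case with dropped-row counts attached.

The contour model restricts to the ring strata and regresses slope on
**proximity** (ring 10 → 1, ring 1 → 10), so a positive coefficient
means more leakage nearer the WMH edge; adjustment: age, Fazekas, mean
arterial pressure, subtype, smoking.

The cognition models regress 1-year ACE-R on standardized WMH leakage,
NART, Fazekas, age and hypertension; with `include_baseline = TRUE`
baseline ACE-R is added, making the leakage coefficient a *change*
effect; `by_subtype = TRUE` splits the leakage effect into lacunar and
cortical components.

A one-stage longitudinal alternative (`fit_leakage_longitudinal()`:
enhancement ~ time × covariates with a random per-patient time slope) is
provided; the two routes agree in sign and magnitude on synthetic
curves, which the test suite checks per tissue with matched adjustment
sets. The sagittal-sinus reference enters the models as a covariate, not
as a subtraction — adjustment, not correction.

# The synthetic cohort generator

## What it emulates

- **Acquisition**: 20 dynamic frames at 1.2 min spacing (24 min), flips
  2°/12°, TR 8.2 ms, relaxivity 3.6 mM⁻¹s⁻¹ (gadolinium chelate at
  1.5 T). Frame spacing is configurable and no estimator assumes
  uniformity.
- **Blood pool**: linear upslope to a 5 mM plasma peak at 1 min, then
  bi-exponential washout (half fast at 5 min⁻¹ — the first pass clears
  within the first frame interval — half slow at 0.003 min⁻¹). The form
  is a package choice; only the qualitative shape (peak then decline,
  while leaky tissue keeps enhancing) is constrained by the physiology
  being emulated. A single haematocrit constant (0.45) converts plasma
  to whole-blood concentration for the sinus. Contrast dose enters only
  through the bolus amplitude; per-patient amplitude varies by 5% SD
  and drives the sinus covariate.
- **Tissue truth**: the leakage preset is specified on the *reported
  slope scale* — distant NAWM 0.15, DGM 0.10, less/intense WMH
  0.30/0.38, CSF 0.55, infarcts 0.7–0.8 (all ×10⁻³ min⁻¹), with a
  0.0099×10⁻³ increment per contour step toward the WMH — and converted
  to $K^{trans}$ through a per-compartment sensitivity
  $\kappa = \partial(\text{slope})/\partial K^{trans}$ computed from
  the forward model by finite difference. The forward model is nearly
  linear in $K^{trans}$ at these concentrations, so the printed effect
  sizes are exact on the slope scale (the resulting transfer constants,
  ~0.8–1.6 × 10⁻⁴ min⁻¹, sit in the low-permeability regime).
- **Covariate effects**: per-tissue slopes change with age (per 5 y),
  Fazekas score, subtype, hypertension, blood pressure, smoking and
  tissue T1, at the magnitudes in `covariate_effects()`; MD and T1 rise
  and FA falls with Fazekas in white matter compartments. Patient-level
  variation decomposes into a shared intercept (SD 0.10×10⁻³), a
  patient-by-tissue biological deviation (SD 0.25×10⁻³, homoscedastic
  across compartments so the mixed model is correctly specified), and a
  small ROI-mean measurement error (SD 0.02×10⁻³ — small because ROI
  means average thousands of voxels, which also keeps
  errors-in-variables attenuation of the cognition effect negligible).
- **Covariate distributions**: age uniform on [34, 97], 46% lacunar,
  Fazekas weighted toward low-moderate burden, hypertension 60%,
  smoking 25%, MAP ~ N(100, 12), pulse pressure ~ N(60, 14),
  NART ~ N(112, 9). These are loosely matched descriptives, not fits.
- **Cognition**: baseline ACE-R ~ 87 − 0.15·(age−66) + 0.25·(NART−112)
  + N(0, 3); 1-year ACE-R adds 0.95 × baseline, a −0.3/point Fazekas
  term, and −1.89 points per SD of *true* WMH leakage (or
  subtype-specific coefficients), with N(0, 3) residual; scores are
  truncated to [0, 100]. The location is deliberately placed clear of
  the ceiling so truncation stays a rare guard (<2% of draws): real
  post-stroke cohorts sit closer to the instrument ceiling, which
  attenuates linear estimates — a known limitation of what these
  recovery tests show about real data.
- **Noise**: Gaussian on the complex channels → Rician magnitude by
  default (plain Gaussian available for analytic tests), at an SNR
  referenced to mean pre-contrast brain signal.
- **Diffusion**: per-compartment prolate axisymmetric tensors built to
  hit target MD/FA exactly
  ($\delta = FA/\sqrt{3-2FA^2}$, $\lambda_1 = MD(1+2\delta)$,
  $\lambda_{2,3} = MD(1-\delta)$); MD is reported in 10⁻³ mm²/s
  (= 10⁻⁹ m²/s), matching the numeric convention of the field's plots.

Anatomy is schematic by design: nested ellipsoids (CSF rim, NAWM, a
central WMH with an intense core scaling with Fazekas score, deep grey,
one or two infarcts, a sinus tube). There are no realistic templates, no
registration, no partial-volume mixing, no arterial-input deconvolution,
no Rician-bias correction. Passing recovery tests therefore demonstrates
the *estimation machinery* is sound under the stated generative
assumptions — not that segmentation or registration errors in real data
are handled.

## Two simulation routes

The voxel route (`simulate_dce()`, `simulate_dwi()` on
`generate_anatomy()` grids, default 44×44×28 at 1 mm) exercises the full
image pipeline and is used for the qualitative contracts, ordering
checks and determinism. For replicate-heavy recovery studies the
tissue-level route (`simulate_cohort_slopes()`) evaluates the same
forward model on compartment-mean curves and adds ROI-level noise —
mathematically the same measurement with the voxel-averaging step done
analytically. Recovery studies use 100 replicate cohorts of n = 200 on
the tissue route; ordering checks use six patients on 64×64×32 grids
(large enough to hold all ten rings); determinism uses two patients.
These sizes are the package's validation design.

## The ordering preset

`preset_ordering_cohort()` gives a deterministic cohort (identical
covariates except Fazekas and age; all variance components zero) on
which contour profiles are exact. It samples the burden groups at
Fazekas 2, 4 and 6: with the default per-tissue Fazekas effects (WMH
0.104×10⁻³ vs NAWM 0.024×10⁻³ per point), WMH leakage falls *below* the
contour-1 level for scores under ~2 — the lesion converges toward NAWM
as burden vanishes — so strict monotonicity into the lesion is a
moderate-to-high-burden property, while high-vs-low group ordering
holds at every stratum regardless.

# Numerical and edge-case policy

- Negative concentrations (possible when covariate extrapolation drives
  a truth $K^{trans}$ negative) are clipped at zero in voxel simulation,
  with a warning count; the tissue-level route keeps the linear model
  (a measured slope may legitimately be negative).
- Diffusion tensors with negative eigenvalues are flagged and excluded
  from MD/FA summaries (flag-and-exclude, not clip); non-positive
  signals invalidate the voxel; counts are reported.
- Empty labels are omitted with a log entry; empty WMH (Fazekas 0)
  labels all NAWM distant with a warning; an empty sinus mask is an
  error, because the intravascular reference is mandatory.
- Rank-deficient fixed-effect designs abort with the collinear terms
  named. A single tissue stratum must be requested explicitly
  (`single_stratum = TRUE`) and is fitted by OLS, since a patient
  random intercept is not identifiable from one row per patient.
- The six-direction default gradient scheme is the classic DTI set; a
  six-point spherical spiral does not determine the tensor (rank 5).
- All label volumes share one grid; geometry mismatches are errors, not
  silent resampling. Every run directory contains the serialized config
  and an MD5 manifest; identical config + seed gives identical
  manifests.

# Known limitations

- The per-tissue T1 effects in the truth are adjusted by a *single*
  pooled T1 covariate in the models (as is conventional); because T1
  also rises with Fazekas score in white matter, a small fraction of
  the Fazekas effect is re-attributed, biasing the NAWM Fazekas
  coefficient slightly toward zero (~10–15% at the defaults) while CI
  coverage stays conservative. This mirrors the situation any real
  analysis with a pooled T1 adjustment faces.
- Wald/normal inference ignores small-sample degrees-of-freedom
  corrections; with ~200 patients this is immaterial, at n ≈ 20 it is
  not.
- Enhancement-slope units are relative-enhancement per minute; any
  absolute comparison across protocols inherits the normalisation
  choice (`normalize = "difference"` exists but changes the scale).
- The simulator's compartments are internally homogeneous; within-tissue
  heterogeneity, partial volume and motion are absent, so real-data
  variances will exceed the synthetic ones at matched SNR.
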