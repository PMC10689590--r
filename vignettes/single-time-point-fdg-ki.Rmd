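---
title: "Single-time-point quantification of cerebral FDG net influx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-time-point quantification of cerebral FDG net influx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Fully quantitative FDG-PET of the brain estimates the net influx constant
$K_i$ (mL g$^{-1}$ min$^{-1}$) — the Patlak slope, proportional to the
cerebral metabolic rate for glucose — from a dynamic recording and an
arterial input function. Long-axial-field-of-view scanners make an
image-derived input function (IDIF) from the descending aorta routine, but a
60--70 min dynamic acquisition per patient remains the bottleneck. This
package implements, and makes testable, a family of estimators that recover
$K_i$ from a *single late frame* (52--67 min post-injection) plus population
pharmacokinetic knowledge of the blood curve.

## The input-function model

After a bolus, the arterial FDG concentration is modelled as a
tri-exponential,

$$C_a(t) = A e^{-\lambda_1 t} + B e^{-\lambda_2 t} + C e^{-\lambda_3 t},
\qquad t \ge t_\mathrm{appear},$$

whose phases are conventionally attributed to mixing of the bolus in the
blood pool ($\lambda_1$), partitioning of plasma FDG into bodily tissues
($\lambda_2$), and renal elimination ($\lambda_3$). `decompose_triexp()`
fits this by the classical method of residuals on semi-log plots: the slow
phase is regressed on the late window (default mid-times in [35, 67] min),
subtracted, the intermediate phase fitted to the positive residuals in
[2, 20] min, and the fast phase to a second round of residuals between the
time-to-peak and 2 min.

Two numerical choices matter here:

* **Iterative re-stripping.** One-pass peeling leaves a bias in
  $(C, \lambda_3)$ whenever the intermediate phase has not fully decayed by
  35 min; with realistic $\lambda_2 \approx 0.1$--$0.2$ min$^{-1}$ and
  $B \approx C$ this bias can reach several percent. After the initial
  peel, each phase is therefore refitted on the data minus the other
  phases' current estimates (`refine = 5` passes). On noiseless model data
  this drives the cross-phase contamination to numerical zero while leaving
  degenerate (bi-/mono-exponential) fits untouched.
* **Degradation instead of failure.** If fewer than three residuals exceed
  a relative floor ($10^{-6}$ of the curve maximum) at some stage, that
  phase's amplitude is set to zero and the result flagged, so clinically
  noisy curves still decompose.

The windows are configuration knobs. The slow-phase window defaults to
[35, 67] min; a 30-min lower bound is equally defensible and can be passed
as `tail_window = c(30, 67)`. The intermediate and fast windows have no
canonical published values; [2, 20] and (peak, 2] min bracket the visual
structure of typical decompositions on a schedule with 2-min frames in that
range.

## Input metrics and the late-point abscissa

From a decomposed blood curve, `compute_input_metrics()` reports:

* $\mathrm{AUC}(0\!-\!67)$ — the measured plasma integral, by the
  trapezoid over frame mid-times with a zero anchor at the appearance time
  (beyond the last mid-time the final frame average is carried to the frame
  end, matching how frame averages tile the recording);
* $C_a(52\!-\!67)$ — the unweighted mean over frames whose mid-time lies
  in the closed window [52, 67] min (a time-window definition rather than
  "the last three frames", so arbitrary schedules work);
* $\theta(52\!-\!67) = \mathrm{AUC}/C_a$ — the normalized arterial
  integral (min), the Patlak abscissa of the late point;
* mono/bi/tri-exponential AUC *recovery percentages* — the analytic
  integrals of the 1-, 2- and 3-term models from the appearance time,
  as a percent of the measured AUC.

The identity $\theta \cdot C_a = \mathrm{AUC}$ holds to machine precision
by construction and is asserted in the tests.

## Patlak analysis, full and two-point

`patlak_full()` regresses $C_T(t_j)/C_a(t_j)$ on
$\int_0^{t_j} C_a\,d\tau / C_a(t_j)$ for frames with mid-time $\ge 12$ min,
by unweighted ordinary least squares; the slope is $K_i$, the intercept the
distribution volume $V_D$. The 12-min bound is interpreted on mid-times and
is configurable. `patlak_two_point()` is the degenerate two-point version
used by all simplified methods:
$K_i = (V_T - V_D)/\theta$, a line through a fixed population intercept
$(0, V_D)$ and the single late point $(\theta, V_T)$, with
$V_T$ the late tissue-to-blood concentration ratio.

The four estimators differ only in how they obtain $\theta$ without the
full dynamic blood curve:

| Method | Needs | $\theta$ estimate |
|---|---|---|
| M1 | blood frames 35--67 min | analytic AUC of the fitted tail term, scaled by the population recovery fraction, over $C_a(52\!-\!67)$ |
| M2 | one late frame | site regression AUC vs $C_a(52\!-\!67)$ |
| M3 | blood frames 35--67 min | site regression $\theta$ vs $\lambda_3$ |
| M4 | one late frame + age | site regression $\theta$ vs age |

Method 1's tail integration starts at `t_appear_default = 0.5` min, a
typical appearance time, because a single-frame protocol measures none.
Method 2's regression intercept is bound to the concentration scale of its
source data; the calibration carries a `units_note` and `method2()` refuses
a mismatched scale rather than silently mixing units.

## Site calibrations

`default_calibration("aarhus")` and `"bern"` ship the published population
coefficients (regression lines for $\lambda_3$ vs age, AUC vs $C_a$,
$\theta$ vs $\lambda_3$, $\theta$ vs age; the late-term AUC recovery
fraction; $V_D = 0.55$ mL g$^{-1}$). `fit_site_calibration()` refits all of
them from any cohort by simple OLS; because an OLS line passes through the
predictor/response means, a refitted calibration is automatically unbiased
on its own cohort mean — the property that also makes the shipped
coefficients reproduce the published population means when evaluated at the
published mean predictors. `correlation_matrix()` reports the Pearson
correlation structure of the per-subject parameters with uncorrected
two-sided $p$ values (t distribution, $n-2$ df) and tier flags at 0.05,
0.002, 0.0002 and $10^{-5}$; no multiplicity correction is applied, the
tiers make the penalty explicit instead.

## The virtual cohort generator

`generate_cohort()` exists so that every pipeline stage is testable without
patient data. Per subject it draws:

* age $\sim N(56.5, 14.1^2)$ (Aarhus) or $N(59.7, 15.2^2)$ (Bern), clipped
  to [20, 90] years;
* $\lambda_3$ from the site's age line plus Gaussian scatter (SD 0.0022 /
  0.0019 min$^{-1}$, the residual after removing the age trend from the
  published population SD);
* amplitudes and fast/intermediate rates: $C \approx 5$ (arbitrary
  concentration), $B/C \approx 0.9$--$1.0$, $A/C \approx 11$--$12$,
  $\lambda_1 \approx 3$, $\lambda_2 \approx 0.15$ min$^{-1}$, each with a
  modest lognormal CV. **These are simulator assumptions, not published
  facts** — no population values for the fast phases exist. They were
  chosen analytically (from the closed-form exponential integrals) so that
  the cohort-mean mono/bi/tri AUC recovery fractions land in the mid-80s /
  mid-90s / near-100 percent range and the mean $\theta$ near 110 min
  (Aarhus) and 101 min (Bern), the published population scale;
* appearance time $\sim N(0.24, 0.05^2)$ min;
* regional irreversible two-tissue-compartment parameters: GM
  $K_1 = 0.102$, $k_2 = 0.185$, $k_3 = 0.095$; WM $K_1 = 0.054$,
  $k_2 = 0.106$, $k_3 = 0.0382$ (means; lognormal CVs 15/10/20%), giving
  true $K_i = K_1 k_3/(k_2+k_3) \approx 0.035$ / $0.014$ and
  $K_1/k_2 \approx 0.55$ / $0.51$ mL g$^{-1}$. Draws violating
  $K_i \in [0.005, 0.06]$ or $K_1/k_2 \in [0.3, 0.8]$ are rejected and
  redrawn.

Frame values are *analytic frame averages* of the closed-form curves (the
tissue response to an exponential-sum input is itself an exponential sum,
integrated exactly per frame), not point samples — while the analysis side
uses mid-times, a deliberate mismatch that emulates real PET framing. Noise
is multiplicative lognormal with unit mean and constant CV (default 3%),
simpler than count-rate-weighted PET noise but adequate for desk-scale
validation. The blood volume fraction in tissue is zero, matching the
region-level analysis the estimators target.

### What the simulator does *not* emulate

* A rising bolus peak: the tri-exponential decays from the appearance time,
  so time-to-peak structure, dispersion and delay are absent.
* Spillover/partial-volume effects on the IDIF, plasma-to-whole-blood
  ratios and metabolites (negligible for FDG in the aorta).
* The theoretical Patlak ordinate intercept of an irreversible
  two-tissue-compartment tissue without blood volume is
  $K_1 k_2/(k_2+k_3)^2$ — about 0.24 mL g$^{-1}$ for the GM defaults —
  which is *smaller* than the empirical population intercept
  (0.55 mL g$^{-1}$) observed in patients, where blood volume and
  dispersion contribute. The pipeline therefore self-calibrates $V_D$ from
  the cohort's own full-Patlak GM mean when simulating
  (`self_calibrate()`), exactly as the clinical workflow derives its
  population $V_D$ from the full-IDIF regressions; the shipped 0.55
  remains the clinical default. Consequently passing tests demonstrate
  internal consistency of the estimator chain, not the absolute accuracy
  of the published intercept.

Because of these simplifications the simulation reproduces the *scale* of
the published single-time-point errors (single-digit mean percent error in
GM against the full-IDIF reference) but not their exact values, which are
properties of the patient cohorts.

## Problem sizes and tolerances used in validation

The test-suite and the acceptance script work at the published cohort sizes
(52 Aarhus / 24 Bern subjects, 3% frame noise), which run in seconds.
Property suites use ~100 random draws for the decomposition-recovery and
analytic-AUC checks ($10^{-8}$ relative against adaptive quadrature), 20-25
draws for algebraic identities, and machine-precision assertions
($\le 10^{-9}$) wherever a result is exact by construction (Patlak on an
exactly linear construction, OLS through the means, $\theta C_a =
\mathrm{AUC}$).

## Worked example

```{r, eval = FALSE}
library(fdgki)

# a virtual Aarhus cohort with known ground truth
coh <- generate_cohort("aarhus", seed = 1)

# self-calibrated quantification: full Patlak + the four simplified methods
res <- quantify_cohort(coh)
aggregate(cbind(ki, pct_error_vs_full) ~ method + region, res, mean)

# population pharmacokinetics of the blood curves
tab <- cohort_parameter_table(coh$subjects)
colMeans(tab[c("lambda3", "theta_52_67", "recovery_mono")])
correlation_matrix(tab)
```

## Known limitations

* Region-level TACs only; voxelwise (parametric-image) operation would wrap
  the same estimators but is out of scope.
* No reversible-uptake ($k_4$) handling: the estimators assume irreversible
  trapping over the recording, as is standard for 67-min FDG.
* The two-point methods inherit the gray-matter population $V_D$ even for
  white matter, reproducing the known low bias of white-matter estimates.
* Calibrations transfer only within an acquisition protocol; the
  units-binding guard catches scale mismatches but cannot detect subtler
  protocol differences.
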