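---
title: "First-phase ejection fraction and ventricular-arterial coupling from aortic waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{First-phase ejection fraction and ventricular-arterial coupling from aortic waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ef1hemo)
```

## The indices

The left-ventricular ejection fraction, LVEF = 100·SV/EDV, summarises
global systolic function but is well known to be load dependent.  The
first-phase ejection fraction, EF1, is the fraction of the end-diastolic
volume ejected up to the time of maximal ventricular fibre shortening,
taken operationally as the time of peak aortic flow:

  EF1 = 100 · SV1 / EDV,   SV1 = stroke volume ejected up to peak flow.

Because early ejection reflects the rate of active fibre shortening
rather than the total excursion, EF1 behaves as a contractility index
that is comparatively insensitive to afterload.  Ventricular-arterial
coupling is quantified in the pressure-volume plane: the end-systolic
pressure ESP is read at the dicrotic notch of the aortic root pressure
wave, the effective arterial elastance is Ea = ESP/SV, the end-systolic
elastance is Ees = ESP/ESV (unstressed volume V0 fixed at 0 mL), and
their ratio Ea/Ees is the coupling index.  With V0 = 0 the chain of
definitions closes algebraically:

  Ea/Ees = ESV/SV  (ESP cancels),   LVEF = 100 / (1 + Ea/Ees).

This package computes all of these from single-beat aortic root pressure
and flow waveforms, estimates LVEF from the pressure wave alone via a
lumped-model method, ships a beat simulator that generates virtual
cohorts with known ground truth, and provides the statistical layer used
to compare EF1 with LVEF across a cohort (standardized regression,
Pearson correlations with Fisher-z intervals, and Dunn-Clark tests for
overlapping dependent correlations).

## The beat simulator

`simulate_beat()` integrates a minimal closed-loop systole: a
time-varying-elastance ventricle, an aortic valve, and a two-element
Windkessel.

* Ventricular pressure: `P_lv(t) = E(t) (V(t) - v0)` with a
  raised-cosine activation `E(t)` rising from `e_min` to `e_max` over
  `t_sys` seconds and relaxing over `t_fall` seconds.  The raised
  cosine is exactly the model class the pressure-only LVEF estimator
  assumes, so estimator-recovery tests are model-matched by
  construction.
* Valve: one-way, with a small constant resistance `r_valve`
  (0.01 mmHg·s/mL by default).  An ideal zero-resistance valve makes
  the lumped system eject with a discontinuous flow step at opening —
  peak flow would sit at the very first sample — so a small resistance
  is required for the flow wave to rise smoothly from zero.  The
  default value keeps the trans-valvular gradient at a few mmHg, as in
  a healthy valve.
* Arteries: compliance `c_art` and resistance `r_art`; diastolic
  pressure decays with the time constant `tau = r_art * c_art`.
* Valve closure: the instant ejection flow returns to zero.  A small
  triangular backflow lobe (0.8% of stroke volume over 12 ms by
  default) models the valve-closing transient; passing it through the
  Windkessel is what imprints the incisura on the synthetic pressure
  wave.  The lobe is attributed to valve closure, not to the
  ventricle, so it does not alter ESV.

Numerics: a classic fixed-step fourth-order Runge-Kutta scheme on the
output sampling grid (500 Hz by default) with four substeps per sample
during ejection, where the valve equation is faster than the sampling
grid.  Isovolumic and diastolic phases are advanced in closed form
(pure exponential decay).  Valve events are snapped to the grid; since
flow approaches zero smoothly at closure the induced volume error is
second order (halving the step moves SV by well under 0.1%).  The
periodic steady state is found by iterating whole cycles on the
diastolic starting pressure with secant acceleration to a tolerance of
1e-8 mmHg, which converges in about five cycles.  Beats are stored
re-origined so that t = 0 is ejection onset.

Ground truth stored per beat includes EDV, ESV, SV, LVEF, tau, ESP at
closure, and the operational Ees = ESP/ESV.  Because closure falls
slightly after peak elastance, this operational Ees equals the
instantaneous elastance at closure and is marginally below `e_max`;
it, not `e_max`, is the reference the estimators are judged against.

### The virtual cohort

`generate_cohort()` draws per-subject parameters from six age templates
(ages 25-75 in decade steps; `age_templates()`), calibrated so the
cohort tracks the expected haemodynamic ageing of healthy adults:
aortic SBP rising ~15 mmHg across the lifespan while DBP drifts down a
few mmHg, roughly constant MAP and heart rate, EDV shrinking ~20%, and
contractility (e_max) rising as compliance falls.  A fixed-range
plausibility filter (aortic SBP within 85-140 mmHg, DBP within
55-95 mmHg) drops extreme draws — a deliberately simple surrogate for
the age-specific population screening a full database would use, since
the reference trial data are not redistributable.  Generation is
bit-reproducible under a fixed seed.

What the generator does *not* emulate: wave propagation and
reflection (no arterial tree), and consequently the morphology of the
measured aortic flow wave.  In large-artery pulse-wave databases the
inflow wave is prescribed, front-loaded, with its peak ~80 ms after
ejection onset; in the lumped model flow timing is emergent, and the
elastance-driven gradient peaks much earlier (~20-35 ms).  Synthetic
EF1 values (~8%) are therefore far below both echocardiographic
normals (~30-40%) and the flow-wave-derived values of the large
database analyses (~50%).  Passing tests on this cohort demonstrate
that the landmark detection, integration, estimation, and statistics
are correct and calibrated on a known-truth system of the assumed
model class — not that the synthetic cohort is a clinical reference
population.  EF1 reference values should always come from measured or
prescribed flow waves.

## Estimating LVEF from pressure alone

`estimate_lvef()` implements the three-step lumped-model method.

1. **Arterial time constant.**  `estimate_tau()` fits
   `ln P(t) = ln P0 - t/tau` by least squares over the diastolic window
   `[t_notch + 0.03 s, beat end - 0.01 s]`; the leading margin skips
   the valve-closure transient.  Results outside 0.3-5 s are rejected;
   a log-linear R² below 0.8 flags the fit as unreliable.

2. **Proportional ejected volume.**  During systole the Windkessel
   relation gives the volume ejected into the arteries up to an unknown
   compliance scale:
   `v_ej(t) = C [P(t) - P(0)] + (C/tau) ∫₀ᵗ P ds`, evaluated with
   C = 1.  The resistive term uses absolute pressure (outflow is driven
   by arterial minus venous pressure, and venous pressure is taken as
   zero); the ejection-onset pressure appears only through the
   capacitive term.

3. **Elastance fit.**  A raised-cosine activation with amplitude,
   width, and onset (V0 = 0) is fitted so that
   `E(t) · (EDV_rel - v_ej(t))` tracks the systolic pressure.  Two
   reductions make this single-beat fit well posed.  First, the
   activation is anchored to peak at end-systole
   (`onset = t_notch - width`) — the usual single-beat assumption that
   end-systole coincides with maximal elastance.  Without the anchor
   the decomposition is unidentifiable: on noise-free model-matched
   beats the free three-parameter fit finds a degenerate optimum in
   which the raised cosine reproduces the pressure shape by itself,
   the volume term contributes nothing, and LVEF is wrong by tens of
   points while the residual is *smaller* than at the true solution.
   Second, for fixed width the model is linear in `amplitude · EDV_rel`
   and `amplitude`, so both are profiled out by linear least squares
   and only the width is searched (golden-section within 0.1-0.6 s).
   LVEF = 100·(1 - ESV_rel/EDV_rel); the compliance scale cancels in
   the ratio, which is also why LVEF is invariant to rescaling the
   pressure waveform.  Estimates outside (5, 95)% are flagged
   implausible.

On 50 noise-free simulated subjects the estimator recovers LVEF with a
mean absolute error of ~1.5 percentage points (maximum ~3), tau to
numerical precision, and EF1 to within 0.01 points of the flow-integral
truth — comfortably inside the ~5.6% in-vivo error reported for
pressure-only LVEF estimation of this kind.

## Landmarks and EF1 conventions

* Peak flow: global maximum of the flow wave, earliest sample on ties.
* Ejection end for total-SV integration: first zero-crossing of flow
  after the peak (linearly interpolated), or the beat end; the small
  negative closure lobe is excluded from numerator and denominator
  alike.  Because the proportional area estimate is rescaled to the
  subject's tabulated SV, the denominator convention largely cancels;
  consistency matters more than the choice.
* Area fractions use trapezoidal integration; a cut time between
  samples splits the trapezoid by linear interpolation, making results
  bit-reproducible.
* Dicrotic notch: searched within 350 ms after peak flow.  (With peak
  flow tens of ms into an ejection of ~280 ms, the notch sits ~200 ms
  or more after the anchor, so a substantially shorter window could
  never contain it.)  The detector takes the first local pressure
  minimum; on smooth Windkessel-generated beats, where closure leaves
  only a curvature transient, it falls back to the largest *interior*
  maximum of the second derivative.  A boundary maximum is rejected as
  "no notch", since a smoothly convex decay maximises curvature at the
  window edge without any landmark being present.

## The statistical layer

All regression variables are z-scored (sample SD), so a
single-predictor standardized coefficient equals the Pearson
correlation — an identity the tests check to 1e-10.  Diagnostics follow
the usual battery: VIF (flag above 10), Durbin-Watson, maximal Cook's
distance, residual normality by the Anderson-Darling statistic (flagged
"ok" above p = 0.01), and the spread-location slope (flagged "ok" below
|0.1|); the numeric thresholds stand in for what are usually visual
checks.  Pearson correlations carry Fisher-z confidence intervals,
`tanh(atanh(r) ± z/√(n-3))`, clamped at ±1.

Comparing the correlation of one variable (say Ees) with EF1 against
its correlation with LVEF uses correlations measured on the same
subjects, so the two are themselves correlated.  `dunn_clark_test()`
Fisher-transforms both and scales their difference by a covariance term
built from the inter-correlation of the two outcomes.  The default
variant pools the two correlations (`rbar = (r1 + r2)/2`) inside the
covariance — the common modern form — and the original per-correlation
covariance is available as `method = "dunn1969"`; the two differ
negligibly at cohort sizes (z 1.808 vs 1.813 on a worked n = 103
example).  Under a simulated trivariate-normal null the type-I error at
alpha = 0.05 is 0.049-0.050.  No multiplicity correction is applied;
alpha = 0.05 two-sided throughout.

With V0 = 0 and ESV derived from the estimated LVEF, Ea/Ees is an exact
monotone function of LVEF, so within this pipeline the LVEF-vs-Ea/Ees
correlation is structurally near -1 over a narrow LVEF range.  In
database analyses the corresponding correlation is attenuated by the
discrete parameter grids of the source simulations; that clustering is
a dataset property the synthetic cohort does not reproduce.

## Problem sizes and run times

The bundled checks use cohorts of 36-70 subjects for waveform and
recovery tests, a 300-subject cohort for the end-to-end summary, 2000
replicates for the type-I-error calibration, and 500 replicates for CI
coverage; each beat simulates in ~15 ms, so the whole battery runs in
well under a minute on one core.  These sizes give binomial/Monte-Carlo
noise comfortably inside the asserted bands.

## Limitations

* The two-element Windkessel has no wave reflection: synthetic flow
  timing (and hence EF1 magnitude) does not match measured aortic
  waves, and the dicrotic notch is a curvature transient rather than a
  sharp incisura.
* V0 = 0 makes Ees operational, not anatomical, and ties LVEF to
  Ea/Ees deterministically.
* The pressure-only LVEF estimator assumes constant arterial
  compliance and the raised-cosine elastance class; violations (e.g. a
  large trans-valvular gradient) bias it low.
* The plausibility filter is a fixed range, not an age-specific
  population screen.
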