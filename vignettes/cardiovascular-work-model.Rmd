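---
title: "Model-based estimation of left-ventricular pressure and myocardial work in aortic stenosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based estimation of LV pressure and myocardial work}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(cvwork)
```

## The problem

In aortic stenosis (AS) the narrowed aortic orifice creates a systolic
pressure gradient between the left ventricle (LV) and the aorta, so the
LV pressure curve — which the pressure–strain myocardial work indices
need — cannot be approximated by cuff pressure as it can in a normal
ventricle.  Measuring it directly requires catheterisation.  `cvwork`
implements the alternative: a closed-loop lumped-parameter model of the
cardiovascular system whose parameters are identified per patient from
sparse observables (systolic/diastolic aortic pressure, echocardiographic
aortic valve area, and — for training data — an invasive LV trace), and
whose simulated LV pressure then feeds the work computation.

## The model

**Electrical activity.** Seven timed automata (sinoatrial node, both
atria, atrioventricular node, upper bundle of His, both ventricles) cycle
through slow diastolic depolarisation, upstroke, absolute and relative
refractory phases; a cell stimulates its neighbours when it completes its
upstroke.  Only the sinoatrial node self-cycles; its period is the heart
period `T`.  The simulation is event-driven and exact, and the LV
activation instants serve both as the QRS fiducials used for signal
synchronisation and as the reset times of the mechanical driver clocks.
Stimulation during the relative refractory phase triggers an immediate
upstroke; delayed-normalisation effects are ignored.

**Cardiac chambers.** Ventricular pressure combines a linear
end-systolic and an exponential end-diastolic pressure–volume
relationship, weighted by a double-Hill driver
$e(t) = k\,\frac{(t/\alpha_1 T)^{n_1}}{1+(t/\alpha_1 T)^{n_1}}
\cdot\frac{1}{1+(t/\alpha_2 T)^{n_2}}$.
The scale $k$ is treated as a derived normaliser fixed so that
$\max_t e(t) = 1$ — the identified parameter set contains
$\alpha_1, \alpha_2, n_1, n_2$ but not $k$, and with this convention
$E_{es}$ is the true maximal elastance.  Atria follow a linear law whose
slope cycles through a Gaussian driver; the Gaussian form is implemented
literally (peak slope $E_{max}+E_{min}$), with a `peak_convention`
switch for the alternative reading in which the peak is exactly
$E_{max}$.

**Valves.** Each of the four valves carries two states: the flow $Q$,
driven by a Bernoulli pressure–flow relation with inertance
($\Delta P = B\,Q|Q| + L\,\dot Q$, $B = \rho/2A_{eff}^2$,
$L = \rho\,l_{eff}/A_{eff}$), and the opening fraction $\xi \in [0,1]$
with first-order pressure-driven dynamics (rate constants $K_{vo}$,
$K_{vc}$).  The effective area interpolates linearly between
$A_{eff,min}$ and $A_{eff,max}$; $A_{eff,min}$ defaults to 0.1% of
$A_{eff,max}$, a negligible leak that keeps $B$ finite at closure.  All
unit conversions (CGS to mmHg·s·mL) happen once, in
`bernoulli_coefficients()`.  The aortic $A_{eff,max}$ is the
patient-measurable quantity: it is clamped to the echocardiographic AVA
during identification.

**Circulation.** Six vessel chambers (aorta, systemic artery, systemic
vein, vena cava, pulmonary artery, pulmonary vein) with linear elastance
laws, connected by pure resistances in the closed loop
LV → ao → sa → sv → vc → RA → RV → pa → pv → LA → LV.  Two
small non-identified return resistances (vena cava→RA and pulmonary
vein→LA) close the loop; a direct pressure tie would be singular in a
lumped ODE.  The 18 continuous states (10 volumes, 4×(Q, ξ)) are
integrated with `deSolve::lsoda` against a compiled right-hand side; a
pure-R mirror of the same equations (`cvs_rhs_r()`) exists solely as the
independent cross-check used by the tests.

**Blood volume budget.** Initial volumes are distributed from target
filling pressures, with the vessel chambers scaled so the total blood
volume equals `circulation$total_volume` (default 3000 mL).  This makes
the unstressed volumes $V_{d}$ physiologically meaningful — enlarging a
reservoir's unstressed volume removes stressed, pressure-generating
volume from the loop — which matters because four $V_d$ parameters are
part of the identified circulatory subset.

## Default parameters

Defaults describe a resting adult at 60 bpm with a 2.5 cm² aortic valve.
The paper trail for lumped-parameter constants of this model family runs
through supplements we do not ship; the packaged values were instead
chosen in physiologic ranges and calibrated once against the model's
published operating points: the healthy configuration yields a systolic
LV pressure of ~120 mmHg with aortic pressure swinging between ~50 and
~120 mmHg, and reducing only the aortic effective area to 0.75 cm²
yields LV ~150 / aortic ~110 mmHg with a ~40 mmHg transvalvular
gradient.  The key calibrated constants are the aortic and systemic
arterial elastances (2.4 and 3.0 mmHg/mL — stiff, as appropriate for an
elderly AS population with a wide pulse pressure), the systemic
resistance (0.9 mmHg·s/mL) and the LV end-systolic elastance
(3.4 mmHg/mL).  All are exposed through `cvs_params()` as dotted-path
overrides.

```{r nominal}
sim <- cvs_simulate(cvs_params(), beats = 12)
summary(sim)
```

## Myocardial work

Segmental power is the product of strain rate (central differences on
the uniform strain grid; an optional Savitzky–Golay flag exists but the
default is the transparent, unsmoothed estimator) and instantaneous LV
pressure.  Cumulative work integrates power from mitral valve closure
(MVC) to mitral valve opening (MVO).  One sign convention deserves
emphasis: the cumulative trace is oriented so that *shortening against
pressure counts as ascending (positive) work* — the clinical
pressure–strain convention.  With that orientation the constructive /
wasted decomposition behaves as intended: a synchronously shortening
ventricle accumulates all its systolic work in ascending runs
($W_p^S$), its isovolumic-relaxation lengthening in descending runs
($W_n^{IVR}$), and its wasted work is zero.

Within systole (MVC→AVC) and isovolumic relaxation (AVC→MVO) the trace
is partitioned into maximal monotone runs; ascending increments sum to
$W_p$, descending magnitudes to $W_n$, with a dead-band of $10^{-12}$
treating numerically flat steps as run continuation.  Globally,
$GCW = \mathrm{mean}_k(W_{p,k}^S + W_{n,k}^{IVR})$,
$GWW = \mathrm{mean}_k(W_{n,k}^S + W_{p,k}^{IVR})$, and
$GWE = GCW/(GCW+GWW)$, reported in mmHg·%.  When $GCW+GWW=0$ the
efficiency is returned as a flagged missing value.

## Sensitivity screening

`rank_cvs_parameters()` screens the 18 identified parameters
($X_{LV} \cup X_{art}$) plus the aortic effective area with Morris
elementary effects on the transvalvular gradient
$\Delta P = \max(P_{LV}) - P_{ao,sys}$: 10 random one-at-a-time
trajectories on a 4-level grid with step $\Delta = 2/3$ in rescaled
coordinates, ranges ±30% of nominal.  $\mu^*$ is the mean absolute
elementary effect, $\sigma$ the standard deviation of the *signed*
effects (an `abs_sigma` flag gives the literal all-magnitude reading),
and parameters are ranked by the distance
$D = \sqrt{\mu^{*2} + \sigma^2}$.

The screening is evaluated at the AS reference configuration
($A_{eff,max} = 0.75$ cm²), where it is clinically relevant: the
gradient scales as $1/A^2$, so near a healthy 2.5 cm² orifice the area
has little leverage and LV elastance tops the ranking instead, while in
the stenotic regime the aortic effective area dominates, followed by the
LV elastance parameters ($E_{es,lv}$, $\alpha_2$):

```{r morris, eval = FALSE}
mr <- rank_cvs_parameters(cvs_params(valves.aortic.A_eff_max = 0.75),
                          r = 10, seed = 1)
print(mr)
```

## Two-step identification

Identification minimises, with a real-coded evolutionary algorithm
(tournament selection, BLX-0.5 crossover, Gaussian mutation, elitism,
early stop on stall; optional Nelder–Mead polish), a cost in mmHg:

* **Step 1** (training patients, invasive trace available):
  $J_{step1} = J_{PLV} + J_{Pao,sys} + J_{Pao,dias}$, where $J_{PLV}$ is
  the mean absolute error between the measured and simulated LV cycles
  synchronised on the QRS, and the aortic terms are absolute errors of
  the extrema.  All 18 parameters in $X_{LV} \cup X_{art}$ are free
  within ±30% of nominal; the aortic area is clamped to the measured
  AVA, and the simulator runs at the patient's measured cycle length.
  After training, the ventricular estimates are averaged:
  $\bar X_{LV}^* = \mathrm{mean}(X_{LV}^*)$.
* **Step 2** (test patients, non-invasive data only): with $X_{LV}$
  frozen at $\bar X_{LV}^*$, only $X_{art}$ is identified against
  $J_{step2} = J_{Pao,sys} + J_{Pao,dias}$; the fitted model then
  *predicts* the full LV pressure curve.

`mc_cross_validate()` wraps both steps in Monte-Carlo cross-validation:
N random half/half cohort splits; each time a patient lands in a test
set its estimated pressure produces work indices, and per-patient
markers are means over those test appearances.  N defaults to 10
(config-exposed); the cost denominator of $J_{PLV}$ is the sample count
(mean absolute error), equivalent to a duration normalisation up to the
fixed grid.  Every stochastic component (splits, EA, noise) derives its
seed from one master seed.

## The synthetic cohort

Real validation of this pipeline used invasive recordings we cannot
ship, so the package generates virtual AS patients with known ground
truth: each identified parameter is jittered uniformly (default ±15%)
around nominal, the aortic area is drawn from a severe-AS range
(11 of 12 patients with AVA ≤ 1.0 cm², one moderate), the heart period
from 0.8–1.1 s, and the truth is simulated to periodic steady state.
Observables are then degraded to clinical fidelity: the LV trace
resampled at 200 Hz with 1 mmHg Gaussian noise, aortic readings with
2 mmHg noise (clipped to keep systolic > diastolic), and strain at
100 Hz.  Because the lumped model has no regional mechanics, segmental
strain is synthesised from the true LV volume under a self-similar
geometry assumption, $\varepsilon(t) = 100[(V(t)/V_{MVC})^{1/3} - 1]$,
giving physiologic magnitudes (−15 to −30%); segments differ by
amplitude scales (uniform 0.9–1.1), optional dyssynchronous time shifts,
and small additive noise (0.05% SD — strain noise enters the work
decomposition through a derivative, so the transparent default keeps the
noise floor of GWW well below physiologic wasted work).

What passing recovery tests on this cohort shows: that the estimation
machinery — cost construction, EA search, cross-validation bookkeeping,
work computation — recovers pressures and work indices when the data
generating process *is* the model.  What it cannot show: robustness to
model misspecification (real ventricles are not double-Hill elastances),
regional strain heterogeneity beyond amplitude/timing perturbations, or
measurement artefacts beyond additive Gaussian noise.

## Numerical choices

* Integration: `lsoda`, rtol $10^{-6}$/atol $10^{-8}$ for reference
  simulations; identification evaluations relax to $10^{-5}$/$10^{-6}$
  (the costs are means and extrema, insensitive at that level).  Output
  on a uniform 1 ms grid by default (2–4 ms inside identification
  loops).
* Steady state: a run is converged when the beat-to-beat change of both
  the LV pressure maximum and the stroke volume falls below 0.5%; the
  analysis beat is the last complete beat.  From the packaged initial
  conditions 12–15 beats converge; identification evaluations use
  6–12 beats, and recovery studies match the truth-generation settings
  so the cost at the true parameters is numerically zero.
* Valve events: MVC/AVO/AVC/MVO are threshold crossings of ξ at 0.05
  with linear interpolation; the MVC search window starts slightly
  before the QRS because mitral closure accompanies it.
* Monotone runs: strict sign changes with a $10^{-12}$ dead-band,
  ties continue the current run.
* Problem sizes in the test suite: Morris at r = 10 (200 simulations);
  step-1 recovery with EA population 30 × 25 generations plus a 400-step
  polish; cross-validation on 12 virtual patients with N = 3 splits and
  reduced EA budgets (population 20/14) — sizes chosen to exercise every
  stage at full fidelity while keeping the suite comfortably
  desk-runnable.

## Known limitations

* No ventricular interaction (septum/pericardium), baroreflex, or
  respiratory modulation; no regurgitant valves beyond the leakage
  floor.
* $J_{step2}$ constrains 11 circulatory parameters with two scalars;
  the step-2 estimate is regularised only by the ±30% bounds around
  nominal and by freezing $\bar X_{LV}^*$, so individual circulatory
  parameters are not interpretable — only the resulting pressure curve
  and work indices are validated.
* The Morris ranking depends on the reference configuration (see
  above); rankings computed at healthy areas answer a different
  question.
* The synthetic strain surrogate ties all segments to the global volume
  waveform; genuinely regional pathology (post-systolic shortening
  patterns) is outside its expressive range.
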