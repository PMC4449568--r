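---
title: "Model-based non-invasive ICP estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based non-invasive ICP estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicp)
```

## The problem

Intracranial pressure (ICP) is normally 5–15 mmHg supine and rises
dangerously with hemorrhage, edema or tumors, but measuring it directly
requires drilling into the skull. Two signals that *can* be measured
non-invasively carry information about it: arterial blood pressure (ABP,
finger or radial tonometry) and cerebral blood flow velocity (CBFv,
transcranial Doppler at the middle cerebral artery). This package
implements a family of model-based estimators that map (ABP, CBFv) to an
ICP estimate, a lumped-parameter circuit simulator that provides reference
traces for validating them, a synthetic waveform generator so the whole
pipeline runs without clinical data, and the trial protocol used to test
whether an estimator detects the transient intracranial hypertension caused
by a Valsalva maneuver (VM).

## The simplified-resistance (SR) estimator

The intracranial circulation can be abstracted as an electrical circuit:
pressures are voltages, flows are currents, vascular segments are
resistors, vessel walls and the intracranial space are capacitors. The SR
estimator starts from the observation that for the *DC component* of the
signals — everything below 0.2 Hz — every capacitor is an open circuit, and
the circuit collapses to two resistive fragments:

1. an arterial resistance between systemic pressure and the capillary bed,

   $$P_c = P_a - R_a \, Q_{CBF},$$

2. a cerebrospinal-fluid (CSF) divider between the capillary node and the
   venous sinus, formed by the CSF formation resistance $R_f$ and outflow
   resistance $R_o$:

   $$P_{ic} = P_{vs} + (P_c - P_{vs}) \frac{R_o}{R_f + R_o},$$

   a linear interpolation between capillary and sinus pressure (with the
   default constants the interpolation weight is $523/2903 \approx 0.18$).

Flow is not measured directly; Doppler velocity stands in for it through a
proportionality $Q_{CBF} = \alpha \, \mathrm{CBFv}$ with
$\alpha = 0.15$ (ml/s)/(cm/s), consistent with a normal CBF of about
11.67 ml/s at velocities of 70–80 cm/s.

The full pipeline (`sr_estimate()`) is therefore: zero-phase low-pass both
inputs at 0.2 Hz, convert velocity to flow, apply the two closed forms.
There are no parameters to fit per subject, no compliance terms, and the
estimate updates per sample — which is exactly why it can track an ICP rise
within seconds.

Default constants (`sr_params()`): $R_a = 6$ mmHg s/ml, $P_{vs} = 6$ mmHg,
$R_f = 2380$ mmHg s/ml, $R_o = 523$ mmHg s/ml, $\alpha = 0.15$, cutoff
0.2 Hz.

## Comparator estimators

**Pulsatility-index (PI) regression** (`pi_estimate()`). Per beat of CBFv,
$PI = (v_{sys} - v_{dia}) / v_{mean}$ (Gosling's index, with the
end-diastolic convention: the diastolic value is the velocity at the next
beat onset), mapped to ICP by a fixed regression
$ICP = 5.305 \, PI + 4$. PI uses only CBFv morphology; a venous-side ICP
rise that barely alters the velocity waveform is invisible to it.

**Two-element model** (`kashif_estimate()`). Models the path from
middle-cerebral-artery pressure $P_{MCA}$ to ICP as one resistance $R_a$
and one compliance $C_a$:
$Q = (P_{MCA} - P_{ic})/R_a + C_a \, dP_{MCA}/dt$, with ICP held constant
over an estimation window (60 s by default, the length that makes the
method slow to react). Peripheral pressure is first advanced by the
transit-time shift $\tau$ estimated from matched systolic peaks
(`estimate_time_shift()`). Identification is per beat:

* $C_a$ is regressed on the systolic upstroke (top quartile of $dP/dt$
  within the beat), where the compliance branch dominates. The regression
  includes an intercept that absorbs the quasi-constant resistive flow
  during the brief upstroke; without it the resistive contribution biases
  $C_a$ upward by tens of percent even on data generated from the
  two-element model itself.
* $R_a$ is read off two in-beat instants $t_1, t_2$ with near-equal
  $dP/dt$ (within 5% of the beat's $dP/dt$ range), chosen to maximize
  their flow contrast. Because sampled data never give *exactly* equal
  slopes, the residual compliance current is removed explicitly by using
  the compensated flow $\hat Q = Q - C_a \, dP/dt$ in the ratio
  $R_a = \Delta P / \Delta \hat Q$ — exact on model data for any pair, and
  the same $\hat Q$ is what the beat-ICP formula
  $P_{ic} = \overline{P_{MCA}} - R_a \overline{\hat Q}$ needs anyway.
* Beats with no valid pair (e.g. capacitor-only flow, which has no
  resistive contrast) report `NA` for $R_a$ and are skipped in the ICP
  series; `kashif_fit_beats()` exposes the per-beat identification.

On data generated from the two-element model itself
($C_a = 0.15$ ml/mmHg, $R_a = 6$ mmHg s/ml, ICP 10 mmHg, 0.02 ml/s of
sensor-scale flow noise) the estimator recovers both parameters within a
few percent and ICP within a fraction of a mmHg. With substantially larger
flow noise the single-sample pair selection degrades gracefully but
noticeably (the max-contrast rule preferentially picks favorable noise);
this is a known fragility of two-point identification, not of the
implementation. On data from the *full* circuit, which the two-element
model misspecifies, the method overestimates ICP considerably — consistent
with its behavior on human recordings.

## The reference circuit

`ursino_simulate()` implements the classic lumped model of intracranial
hemo- and hydrodynamics as a linear, time-invariant network with five
pressure nodes (proximal arterial, capillary, proximal venous, venous
sinus, intracranial), series resistances
$P_a$–$R_1$–$P_1$–$R_2$–$P_c$–$R_{pv}$–$P_v$–$R_{dv}$–$P_{vs}$–$R_{ve}$–$P_{cv}$,
the CSF loop $P_c$–$R_f$–$P_{ic}$–$R_o$–$P_{vs}$, arterial and venous
compliances referenced to the intracranial node, and the intracranial and
extracranial compliances to ambient. Under DC this reduces exactly to the
SR model's two fragments with $R_a = R_1 + R_2 = 6.04$ mmHg s/ml. The
nonlinear features of the original model (pressure-dependent intracranial
elastance, collapsible bridging veins, autoregulation) are deliberately
out of scope: the parameter table is constant and the reduction assumes
linearity.

Two constants deserve a note: the CSF outflow resistance is 526 mmHg s/ml
in the circuit parameter table but 523 in the SR constants; both printed
values are respected in their own contexts (the difference moves the SR
output by under 0.03 mmHg at a capillary pressure of 30).

**Integration.** The network is stiff — CSF resistances are three orders of
magnitude above vascular ones — but also LTI, so instead of a stiff ODE
solver the simulator uses the exact first-order-hold discretization: the
matrix exponential of the Van Loan augmented system is computed once per
sampling interval, and the five-dimensional state is propagated sample by
sample with inputs interpolated linearly within each step. This is exact
for piecewise-linear inputs, unconditionally stable, and fast enough to
run the thousands of 45-s trials the calibration experiments need. The
test suite cross-checks it against `deSolve::lsoda` at tight tolerances
and against the closed-form resistive steady state (`ursino_steady_state()`,
itself verified against a Gauss–Seidel relaxation oracle and nodal current
conservation below $10^{-9}$ ml/s).

**Initialization.** The state starts at the resistive steady state of the
*record-mean* arterial pressure. Starting from the first raw sample — a
diastolic value well below the DC trend — would charge the slow CSF mode
(intracranial compliance against $R_f/R_o$, time constant of hundreds of
seconds) and tilt the entire recording; that drift is invisible to the eye
but large enough to destroy the calibration of a paired test between
early-trial and mid-trial windows.

A consequence of the slow CSF mode worth knowing: a 15-s venous-pressure
step (the VM surrogate) does *not* reach its steady-state ICP response.
The fast part of the rise comes through capacitive coupling of the
proximal venous node (roughly $C_{vi}/(C_1+C_2+C_{vi}+C_{ic}) \approx 0.3$
of the step), while the resistive completion creeps in on the CSF time
scale. The simulated VM rise is therefore a fraction of the steady-state
prediction, which the tests treat as an upper bound rather than a target.

## The synthetic generator

`synth_abp()` builds pulsatile ABP as an asymmetric-Gaussian pulse per
beat (fast upstroke peaking a quarter into the cycle, slower monotone
runoff), scaled to the configured pulse pressure and centred so each full
cycle averages to the configured mean. Defaults: 100 Hz sampling (the
estimators operate on sub-0.2 Hz trends, so acquisition-grade 1 kHz adds
nothing but runtime; `fs` is configurable), heart rate 70 bpm with 2%
beat-to-beat jitter, mean ABP 90 mmHg, pulse pressure 40 mmHg, 1 mmHg
white measurement noise, 1 cm/s CBFv noise.

Two generator properties exist specifically so that fixed-window analyses
are statistically honest:

* recordings start at a uniformly random beat phase, and
* beats are centred by the full-cycle shape mean, not by the mean of the
  samples that happen to fall inside the record.

Without them, every trial cuts the protocol windows at identical beat
phases and the partial-beat content of a window becomes a deterministic
offset rather than zero-mean noise; a paired test across trials then
rejects a true null essentially always (the bias is only ~0.003 mmHg, but
the per-trial noise it is compared against is of the same size). For the
same reason `synth_vm_trials()` draws each trial's heart rate uniformly
from 60–80 bpm, emulating the trial-to-trial heart-rate variability any
repeated human recording session has.

`synth_vm_trial()` produces a 45-s trial: ABP from the generator, then the
circuit simulator driven by that ABP while the VM raises the central
venous source by `vm_pvs_delta` (default 10 mmHg) and systemic pressure by
`vm_abp_delta` (default 10 mmHg) during the 15–30 s window, with 1-s
linear ramps starting at each window edge (the up-ramp completes before
the analysis window opens at 20 s; the down-ramp falls inside the excluded
first 10 s of the recovery phase). True ICP is the simulated intracranial
node — its rise follows from the circuit, not from an imposed shape — and
CBFv is simulated flow divided by $\alpha$ plus noise. The magnitude of
the VM venous rise is a free parameter of the synthetic protocol: the
actual ICP excursion of a real maneuver varies between subjects and is not
measurable non-invasively, so 10 mmHg is a plausible convention, not a
measured value.

What the generator does **not** emulate: respiratory and Mayer-wave
baseline variability, motion artifacts, probe repositioning, autoregulatory
feedback, and the phase-IV overshoot physiology of a real VM. Passing the
synthetic experiments therefore demonstrates internal consistency of the
estimators with the circuit model and correct statistical behavior of the
harness — not clinical accuracy against invasive ICP, which no synthetic
test can establish.

## The evaluation protocol

`segment_trial()` encodes the fixed 45-s protocol — 15 s rest, 15 s VM,
15 s rest — excluding the first 5 s of the maneuver and the first 10 s of
the later rest as transition states, so the analysis windows are [20, 30) s
and [40, 45) s. The resting reference for the paired test is the *first*
rest phase, which recovery cannot contaminate (the late-rest mean is
computed and reported but not tested by default). Per-beat series assign a
beat to the window containing its onset; RMSE and window means resample
per-beat series by previous-value hold and per-sample series linearly.

`run_vm_experiment()` applies each estimator to every trial, summarizes
per-method phase means as mean ± sd to one decimal, and runs the
one-tailed paired t-test of VM > rest (`paired_t_one_tailed()`, delegating
to `stats::t.test`; zero-variance differences are reported as an explicit
degenerate case rather than an infinite statistic). The two-element window
is overridden to 5 s here: a 60-s constancy window cannot subdivide a 45-s
trial and would reduce the method to a single number per trial.

## Problem sizes and runtime choices

The validation experiments are sized for a desk run: 20 recordings of 60 s
at 100 Hz for the simulation-RMSE check, 20 seeds for parameter recovery,
one 20-trial subject for the VM detection check and 200 simulated
null subjects (4000 trials) for the type-I calibration. On one CPU the full
test suite completes in about 2.5 minutes, dominated by the null
calibration.

## Known limitations

* All circuit elements are linear and constant; none of the conclusions
  transfer to regimes where intracranial elastance or autoregulation
  matter.
* The SR venous sinus pressure is a fixed constant (6 mmHg); a real VM
  raises it, so the SR estimate understates the true excursion even while
  detecting it reliably — the detection test is about discrimination, not
  calibration of the rise.
* The two-element identification is noise-fragile at the single-beat
  level, and on full-circuit data it inherits the model misspecification
  bias described above.
* Absolute validation against invasively measured ICP is out of scope by
  construction.
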