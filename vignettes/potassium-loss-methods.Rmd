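---
title: "Modelling potassium loss in acute myocardial ischemia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling potassium loss in acute myocardial ischemia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Within minutes of a coronary occlusion, potassium accumulates in the
interstitium of the affected myocardium. The extracellular concentration
[K+]o follows a characteristic triphasic time course — a rapid primary
rise, a plateau around 10-12 mmol/L, and a slower secondary rise — and, in
regional ischemia, a spatial border zone (BZ) of roughly 1 cm forms
between normal tissue and the maximally hyperkalemic central ischemic zone
(CIZ). Hyperkalemia depolarizes the resting membrane, shortens the action
potential, slows conduction and promotes re-entrant arrhythmias, so the
ionic mechanisms behind it are of direct clinical interest, yet they
cannot be resolved experimentally: no preparation allows simultaneous
recording of individual transmembrane currents, action potentials and
[K+]o in ischemic tissue.

`kloss` implements a coupled cell-and-tissue model designed to dissect
these mechanisms: an ischemia-modified human ventricular cardiomyocyte
with a dynamic extracellular cleft potassium concentration (the "0D"
model), optionally embedded in a 4-cm one-dimensional strand whose distal
half becomes ischemic while extracellular potassium diffuses and drifts
along the fiber (the "1D" model).

## The cell model and its ischemia interventions

The baseline electrophysiology is the O'Hara-Rudy endocardial human
ventricular model: 15 sarcolemmal currents, CaMK signalling, subspace
calcium handling and SR release/uptake. Seven of its currents carry
potassium: IKr, IKs, Ito, IK1, IKb, the potassium component of the L-type
current (ICaK), and the NaK pump (the only K+ influx pathway, 2 K+ per
cycle). Ischemia is imposed through five prescribed metabolic drivers —
[ATP]i, [ADP]i, pHi, pHo, [LPC]i — that act on the membrane via seven
interventions:

1. **IKatp**, the ATP-sensitive potassium current (absent from the
   baseline model), with Ferrero-type gating: an ADP-dependent
   half-saturation and Hill coefficient for the ATP block, a weak
   power-law dependence on cleft [K+]o, and ohmic driving force
   (Vm - EK). The gating is steepened (`katp_h_mult`) so the current is
   essentially silent at the normoxic ATP/ADP ratio.
2. **NaK pump scaling** `fNaK(ATP, ADP)`: a saturating ATP activation
   times an ADP product-inhibition term, both normalized to 1 at the
   normoxic anchor (10 mmol/L, 15 umol/L).
3. **Sarcolemmal Ca pump scaling** `fpCa(ATP)` and
4. **SERCA scaling** `fup(ATP)`: mild saturating ATP dependences.
5. **Acidosis factors** on ICaL, INa, INaL, INaCa and INaK: linear
   fractional reduction per pH unit below the normoxic anchors, floored
   at 0.05. (The sodium/calcium exchanger is scaled as INaCa; the model
   has no separate acidosis action on the ICaNa component of the L-type
   current.)
6. **LPC factors** on INa (depression) and INaL (enhancement), linear in
   the LPC excess over 2 umol/L.
7. **Dynamic cleft potassium**: d[K+]o/dt = alpha * SumIKx +
   ([K+]b - [K+]o)/tau_wo, where SumIKx = IKr + IKs + Ito + IK1 + IKatp +
   IKb + ICaK - 2 INaK, alpha is the surface-to-cleft-volume bookkeeping
   prefactor and tau_wo the wash-out time constant (15 s under perfusion,
   infinite in no-flow ischemia).

### The INa/INaL realization

The baseline fast sodium current is replaced by the ten Tusscher-Panfilov
formulation (m^3 h j), the standard substitution when the model is used in
tissue, with two calibrated kinetic adjustments: the activation time
constant is scaled by 2.1 so that the strand conducts at 70 cm/s at the
reference conductivity without inflating the diastolic stimulation
threshold, and steady-state inactivation is shifted -5 mV so that
partially depolarized (hyperkalemic) cells lose excitability over the
observed [K+]o range — this is what times the onset of APD alternans. The
late sodium current keeps the baseline kinetics with its conductance
scaled 1.5x and its inactivation shifted +20 mV; together these set the
normoxic APD90 near 289 ms and maintain a late-sodium contribution in
depolarized cells.

### Calibration status of the factor curves

The factor-curve parameters in `cell_params()` are model fits, not
literature constants. They are constrained by their normoxic anchors
(all factors equal 1), by monotonicity, and by a set of observable
outcomes of the control experiment: the balanced normoxic potassium
turnover of 34.5 (umol/L)/s; the fall of the potassium influx rate from
34.5 to ~15 (umol/L)/s within 2.5 min of occlusion; the ~5.8 (umol/L)/s
efflux increases carried by IKatp and IK1 at 5 min; a NaK scaling below
0.5 at 30 min; APD90 shortening from ~289 ms to ~192 ms before alternans;
an alternans episode between minutes 4 and 6; and the [K+]o plateau near
11.7 mmol/L. One parameter deserves emphasis: the cleft prefactor
`alpha` (the Ac/(F vo) group). The printed geometric anchors (cell
surface 0.0152 mm2, cleft volume 13.3 um3) are mutually inconsistent as
dimensional inputs to the cleft balance, so `alpha` is treated as a single
calibrated constant fixed by the normoxic turnover; both raw anchors are
retained in the parameter list for reference.

## The metabolite generator

`metabolite_tables()` ships the five driver time courses as plain CSV
control points (monotone piecewise-cubic interpolation; LPC exactly
linear from 2 to 20 umol/L over 30 min). ATP falls from 10 to 3.5 mmol/L
with its steepest decline between 5 and 15 min; free ADP rises steeply to
~115 umol/L by 8 min, partially recovers, and rises again; pHi falls
7.2 -> 6.0 and pHo 7.4 -> 6.2 with a fast early phase. An alternative,
slower ADP course is selectable for sensitivity runs. These tables are
digitizations of published guinea-pig time courses; their shapes carry
real uncertainty, and the simulated flux decomposition inherits it. What
the generator does *not* emulate: metabolite transport or consumption
kinetics (drivers are prescribed, not mechanistic), catecholamine or
fatty-acid effects, cell-to-cell metabolic variability, and membrane
damage in late ischemia. Agreement of the simulated fluxes with reference
values therefore demonstrates internal consistency of the coupled model
under these prescribed conditions, not validation against independent
ischemic-tissue recordings.

In the strand, ATP/ADP/LPC change stepwise at the metabolic border at
x = 2 cm while pHi/pHo ramp linearly across a 0.5-cm transition zone
(configurable to 0 or 1 cm); the same ramp weight applies to both pH
values.

## Numerics

The cell ODEs are integrated with the hybrid scheme that is standard for
this model family: Rush-Larsen exponential updates for the 28 gate-like
states (unconditionally stable for relaxation dynamics) and forward Euler
for Vm, the eight concentrations, CaMK and [K+]o, with the Euler part
sub-stepped 4-8x whenever |dVm/dt| exceeds 20 mV/ms. The default step is
dt = 0.02 ms for both the isolated cell and the strand; halving it
changes APD90 by under 0.5 ms, and the trajectory agrees with an
independent adaptive stiff solve (deSolve::lsoda on the same right-hand
side) to ~1 mV RMS away from the upstroke. An adaptive-step route was
considered and rejected: the fixed-step scheme matches the tissue
numerics exactly, keeps 0D and 1D behavior bit-comparable, and its error
is quantified by the step-halving test.

The strand uses first-order operator splitting per step: (i) a reaction
update of every node's cell state with its local metabolic state,
including the local cleft source and wash-out; (ii) an explicit
zero-flux diffusion update of Vm (the construction-time guard enforces
dt DV/dx^2 <= 1/2); (iii) every fifth step (default), a conservative
flux-form transport update of [K+]o with diffusion and electromigration,
using face-averaged concentrations and zero total flux through both ends.
The extracellular potential needed for electromigration is taken from the
closed form Vo = -Vm/(1+lambda) + c, which is exact under zero-flux
boundary conditions; the discrete Poisson solve is retained as an
independent cross-check (`extracellular_potential(method = "poisson")`)
and both routes agree to round-off. Vo is gauged to zero spatial mean
(option: zero at the left end). The transport sub-cycling is justified by
the smallness of the transport terms — in the coupled run the local
transport flux rate is orders of magnitude below the transmembrane flux
rates.

Injury current is a postprocessing quantity, DV d2Vm/dx2 on the
second-difference stencil with reflected end stencils; conversion to
uA/mm3 multiplies by Cm (0.01 uF/mm2) and the intracellular
surface-to-volume ratio 363.6 mm^-1.

Degenerate inputs are guarded: non-finite states abort with the offending
variable, negative concentrations after a transport step abort with the
node index (a dt/dx misconfiguration signal), stability violations refuse
to construct the grid, and gates are clamped to [0, 1] after each step
(clamping is inactive in practice; the property suite checks bounds).

## The stimulation protocol

Rectangular pulses, 0.5 ms wide, at twice the normoxic diastolic
threshold. The threshold is measured by `find_diastolic_threshold()` —
bisection to 1% on a single diastolic pulse applied to the steady-paced
cell, with an AP deemed elicited when the peak Vm within 50 ms exceeds
0 mV; the measured value is 48.8 uA/uF, and scenario defaults use
97 uA/uF. In the strand the leftmost node is stimulated (count
configurable). Preset heart rates: 0, 30, 60 (control), 120, 180 bpm.
The simulated behavior is sensitive to the stimulus margin: amplitudes
well above twice threshold keep depolarized cells captured longer and
delay or abolish the alternans episode, which is itself the mechanism of
the [K+]o plateau.

## Analysis definitions

* **Flux rates** (per current): K_FRx = alpha * mean of I_Kx over a
  4-beat window, reported per second; positive = efflux. The runner
  accumulates exact running time-integrals of each potassium-carrying
  current at solver resolution, so windows are evaluated without storing
  microsecond traces. Additivity (total = sum of components) is enforced
  at every report. The sliding-window net-flux series underlies the
  plateau detector (`ko_plateau()`: the longest interval with |net| below
  10% of its post-occlusion peak).
* **Beat metrics**: activation = maximum dVm/dt in the cycle; capture =
  peak Vm > -20 mV within 50 ms of the stimulus; APD90 measured from
  activation to 90% repolarization relative to the beat's own amplitude
  (peak minus pre-stimulus diastolic Vm); DmKL = minimum [K+]o in the
  last 100 ms before the next stimulus.
* **Alternans**: consecutive captured beats with |delta APD90| > 5 ms
  (far above solver noise, far below ischemic alternans magnitude),
  run-length merged; a strict sign-alternating difference sequence is
  labelled "2:2", anything else "complex". Non-captured beats break
  episodes.
* **Border zone**: width = distance from the metabolic border (x = 2 cm)
  to the [K+]o profile peak; an alternative 10-90% rise-span measure is
  reported alongside. Invasion depth = extent of [K+]o elevation more
  than 0.2 mmol/L above bulk into the normoxic segment. CIZ level = mean
  over the distal 0.5 cm.
* **Electrograms**: Vo at a probe site over time, baseline-aligned per
  beat to the mean over the 50 ms before each stimulus (the diastolic
  reference for ST-segment reporting).

## Problem sizes used by the shipped checks

The package's own test suite and the acceptance script run the isolated
cell through the full control protocol (5 min normoxia + 20-25 min of
ischemia at 1 Hz, dt = 0.02 ms) and the strand through short conduction
benchmarks (three beats at dx = 0.25 mm, plus one halved-discretization
variant). The border-zone sensitivity comparisons (reduced conductivity,
enhanced potassium diffusion) use a deliberately scaled-down
configuration — 30 s normoxia + 5 min ischemia, dx = 0.8 mm, dt = 0.1 ms,
transport every other step — chosen so that the compared quantities are
grid-resolved orderings rather than absolute widths; at these settings
the early border zone (~0.7 cm at 5 min) is resolved by ~9 nodes and the
discretization bias is common to all members of the comparison. The
full-resolution 30-min strand experiment is available through the
`1D-control` preset for users with an hour of compute to spend.

## Known limitations

* The ischemia factor curves are calibrated parametric forms; their
  parameters are not independently measured, and other parameter sets
  could reproduce the same outcomes.
* The stimulus charge is booked to intracellular potassium (the baseline
  model's convention, which keeps the paced cell on a limit cycle). A
  monophasic stimulus therefore sustains a small net cleft efflux in
  normoxia, absorbed by wash-out: unidirectional efflux and influx differ
  by roughly the mean stimulus current instead of balancing exactly.
* The plateau net flux is reproduced in sign and order of magnitude
  (tenths of a (umol/L)/s) but is sensitive to the post-alternans APD
  trajectory; see the test suite for the quantitative status.
* One-dimensional tissue only; no anisotropy, no transmural
  heterogeneity, no mechano-sensitivity of the K(ATP) channel, no
  membrane damage, and only potassium is transported extracellularly.
* The alternative human AP model variant is out of scope; the cell model
  interface (a single state vector + parameter list) would admit one.

## Reproducing the headline quantities

`scripts/acceptance.R` reruns the control experiments from scratch and
writes the recomputed quantities as JSON; the README shows a worked
example with the numbers the code prints.
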