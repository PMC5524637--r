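---
title: "Modelling and quantifying calcium cycling in PKP2-deficient cardiomyocytes"
author: "cacycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and quantifying calcium cycling in PKP2-deficient cardiomyocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Cardiomyocyte-specific loss of plakophilin-2 (PKP2) downregulates a
transcriptional network controlling intracellular calcium cycling:
RyR2, Ca~V~1.2, ankyrin-B and triadin transcripts fall, and
calsequestrin-2 protein falls with triadin.  The functional phenotype in
isolated myocytes is distinctive: *less* trigger current but *more*
release - reduced peak L-type Ca^2+^ current with slower inactivation
and preserved total charge, increased SR Ca^2+^ load and free SR Ca^2+^,
larger Ca^2+^ transients, more frequent spontaneous release events, and
an increased excitation-contraction (e-c) coupling gain, especially at
positive test potentials.  `cacycle` packages (i) a voltage-clamped
compartmental model of mouse ventricular calcium cycling with a control
and a PKP2-deficient ("PKP2-cKO") parameter set that reproduces these
directions, (ii) the voltage-clamp protocols used to characterise them,
(iii) the quantification operators for the accompanying cell-level and
tissue-level measurements (transient features, sparks, ratiometric
calibration, ryanodine-binding fits, ECG intervals, dyad ultrastructure),
and (iv) seeded synthetic-data generators so that every operator is
testable against known ground truth.

## The calcium-cycling model

### Compartments and state

The model is the voltage-clamped Ca^2+^ subsystem of a whole-myocyte
formulation.  Membrane potential is an input (the clamp command), so
Na^+^ and K^+^ currents and kinase signalling are omitted: every
simulated result in the package is obtained under voltage clamp, where
those currents do not feed back on the Ca^2+^ machinery.  This choice
reproduces the reported model outputs with roughly a quarter of the
state space of the parent formulation.

Five Ca^2+^ pools are tracked (free concentration, mM): the junctional
cleft facing the dyad, the submembrane space, the bulk cytosol, the
network SR and the junctional SR (jSR).  Rapid-equilibrium buffering is
used in the cleft, submembrane space, cytosol (two buffer classes:
troponin-like high-affinity, plus a low-affinity pool) and in the jSR
(calsequestrin, K~d~ 0.63 mM).  The remaining state variables are the
LTCC gates `d` (activation), `f` (voltage-dependent inactivation) and
`fca` (Ca^2+^-dependent inactivation), and a four-state RyR2 cluster
(rested/open/inactivated/refractory occupancies summing to 1).

### Fluxes

* **L-type Ca^2+^ current.** `I_CaL = g_cal * p_cal * d * f * fca * GHK(V, [Ca])`,
  with a Goldman-Hodgkin-Katz driving force and a junctional/submembrane
  split `f_junc : (1 - f_junc)` (default 0.9).  `fca` senses cleft
  Ca^2+^ with a Hill coefficient of 2.
* **RyR2 release.** Four-state scheme with luminal regulation: the
  opening rate scales inversely, and the inactivation rate directly,
  with a luminal factor that falls as jSR free Ca^2+^ rises past a
  threshold `ec50_sr`.  Release flux is proportional to the open
  fraction, the jSR-cleft gradient and `g_ryr`.
* **CSQ-RyR2 coupling.** Calsequestrin is a negative regulator of RyR2,
  so the luminal threshold scales with CSQ content:
  `ec50_eff = ec50_sr * (csq_total / csq_ref)^csq_sens`.  With the
  default `csq_sens`, the CSQ-depleted variant activates at lower jSR
  Ca^2+^, which is what lets reduced RyR2 abundance coexist with
  *increased* fractional release and gain, as observed.
* **SERCA.** Forward/reverse Hill form, so SR free Ca^2+^ is
  thermodynamically tied to diastolic cytosolic Ca^2+^; uptake reverses
  when the SR is overfilled.
* **SR leak.** Diastolic SR leak is RyR2-mediated, so it scales with
  `g_ryr` (`J_leak = g_leak_sr * g_ryr * ([Ca]_nsr - [Ca]_i)`); its
  product appears in the bulk cytosol.  This carries the observed
  knockout direction: fewer RyR2 mean less leak, hence a fuller SR.
* **NCX and background influx.** An electrochemical NCX expression (fixed
  Na^+^) extrudes Ca^2+^ from the submembrane space; a small background
  Ca^2+^ conductance balances it at rest so that a true fixed point
  exists at the holding potential.

### The PKP2-deficient variant

`make_pkp2cko_params()` applies exactly the documented molecular
changes: calsequestrin to 45.3% of control, LTCC closing rate to 75%,
LTCC current density to 50%, RyR2 flux to 60%.  The reported reduced
LTCC expression in T-tubules has no stated magnitude; it is exposed as
`junctional_shift` (default 0.1, i.e. ten percentage points of LTCC flux
moved from the cleft to the submembrane sarcolemma), configurable per
call.

The control model's baseline values are not printed in the source
study (which defers to its parent formulation); the parameter set here
was reconstructed once, from the physiology of the mouse ventricular
myocyte at room temperature and the study's own quantitative anchor -
the LTCC-only variant (closing rate x0.75, density x0.50) must produce a
peak whole-cell current 72% of control under the current-voltage
protocol - and then frozen.  All values live in one place
(`make_control_params()`) and serialise to flat JSON.

Mechanistically, the 72% arises in the model from the interplay of a
comparatively slow activation gate with calcium-feedback on the current:
early in the step, SR release floods the cleft and curtails the rising
current in both variants; the variant's halved trigger recruits release
later and inactivates `f` more slowly, so its current develops further
along the activation time course before being cut back.  The ratio is a
deterministic, emergent property of the parameter set, not an input.

### Numerics

Integration uses `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`,
output every 0.1 ms by default, split at the discontinuities of the
piecewise-constant clamp command.  The compiled right-hand side is
shared by an independent fixed-step explicit-Euler integrator
(`integrate_model_euler`, `dt = 1e-4` ms) that serves as the brute-force
oracle for the adaptive solver in the test suite (agreement within 0.5%
on peak current and peak transient amplitude).  Steady states are found
by chunked relaxation - convergence is declared when no state variable
moves by more than 1e-8 of its scale over one second of model time -
followed by a Newton polish to machine precision when the hold is
quiescent.  Spontaneous SR discharges at a hold are detected as
excursions of the release flux above five times the 99th percentile of
its quiescent level (re-estimated once after excluding events); if a
hold settles on a discharge limit cycle the gain protocol places each
test step at least 500 ms after the previous discharge and 500 ms before
the next, and aborts with the cycle period if no such window exists.

With sarcolemmal fluxes disabled the model is closed: total Ca^2+^
(free plus buffered, volume-weighted) is conserved to a relative 1e-6
over 10 s, and at any state the rate of change of total Ca^2+^ equals
the signed sum of sarcolemmal fluxes - both are enforced in the tests.

## Protocols

* `run_iv_protocol()`: hold -80 mV (60 s pre-equilibration), steps -60
  to +40 mV in 10 mV increments, 400 ms, 5 s interpulse.  Per step:
  baseline-subtracted peak density, single-exponential inactivation tau
  fitted from the in-step peak to the step end, and charge (trapezoidal
  integral, pC/pF).
* `run_gain_protocol()`: hold -50 mV to steady state (600 s cap), then
  150 ms steps from -40 to +60 mV;
  `gain = (peak [Ca]_i / pre-step [Ca]_i) / |I_CaL,max|`.  Both the
  model's concentration-based gain and the experimental
  fluorescence-based statistic use the same `ec_gain()` ratio; the
  inputs differ (mM vs F/F0), never the formula.
* `run_caffeine_dump()`: caffeine is modelled as an RyR2 open-clamp
  (no binding kinetics - only the peak/baseline ratio is consumed),
  applied until jSR free Ca^2+^ falls below 5% of its pre-dump value.
  In permeabilized mode the sarcolemmal pathways are removed and the
  cytosol exchanges with a clamped bath, which makes the baseline
  identical across variants by construction.
* `run_pacing()`: trains of depolarizing steps (default 0 mV / 100 ms -
  the study does not state the model pacing step, so the default is
  exposed as arguments) at a commanded frequency, preceded by
  unrecorded conditioning beats (default 20) mirroring pacing to steady
  state before recording, with per-beat transient features and flags
  for spontaneous release events during (early after-transient
  analogue) or between (delayed after-transient analogue) beats.

## Quantification operators

Transient landmarks follow the optical-mapping conventions: time to
peak is the minimum-to-maximum rise time; CaD30/50/70 run from the
50%-of-maximum crossing on the upstroke to 30/50/70% recovery toward
the *pre-stimulus baseline* (not a post-event plateau).  A 5-sample
moving average (configurable; disable for analytic traces) precedes
landmark detection, and crossings are linearly interpolated.  Decay
time constants come from nonlinear least squares initialised by
log-linear regression; because an exact initial guess makes the
Gauss-Newton step singular on noiseless data, the start is perturbed by
a few percent and the log-linear estimate is used as a fallback when it
already fits to better than 2% RMS.

Spark detection thresholds the F/F0-normalised line-scan at baseline +
3.8 baseline-SD with a 4-pixel minimum area (a common criterion; the
study states none), using a declared pre-event baseline window, and
reports frequency per 100 um per second.  The ratiometric calibration
is `[Ca] = Kd * beta * (R - Rmin) / (Rmax - R)` with K~d~ = 245 nM;
ratios at or below `Rmin` clip to zero with a flag, ratios at or above
`Rmax` are an error.  Ryanodine-binding curves are fitted with the Hill
equation by Levenberg-Marquardt least squares.  ECG intervals use the
murine Mitchell correction `QTc = QT / sqrt(RR / 100)`, and event
counting uses half-open `[0, w)` windows, so an event at exactly the
window edge is excluded.

Ultrastructure quantification operates on binary masks (manual contour
tracing is upstream of this package).  Connectivity is 8-connected
throughout, with Moore-neighbour boundary tracing - one ordered closed
contour per component - matching the boundary-tracing behaviour of the
original analysis; distances are Euclidean nearest-neighbour distances
between boundary *pixel centres* (no sub-pixel interpolation), averaged
and minimised per dyad.  T-tubule orientation is computed on the
Zhang-Suen skeleton via the structure tensor (Gaussian scale 2 px) and
binned at 2 degrees over [-90, 90) relative to the cell long axis,
counterclockwise positive; angles fold modulo 180 degrees, so a vertical
line reports -90.  Cluster analysis smooths, thresholds (Otsu unless
given), labels 8-connected components above a minimum area, tags
lateral-membrane vs midsection clusters via a region mask, and computes
pixel-intersection overlap areas between channels.

## Synthetic data

`generate()` produces every input the operators consume - line-scan
images, transients, ratiometric records, binding curves, dyad mask
pairs, T-tubule networks, two-channel cluster images, event-time lists
and QT/RR tables - with the generating truth recorded next to the data.
Each dataset draws from its own stream derived from (seed, kind,
replicate), so a fixed seed reproduces a dataset bit for bit and
modules can be tested independently or in combination.
`generate_two_group_study()` emulates the control-vs-knockout designs
(normal samples with a declared effect in SD units) and backs the
type-I-error calibration of the group statistics (5% +/- 1.5% at alpha
0.05 over 1000 null replicates).

The generators emulate the *statistical structure* of the measurements
(event counts and amplitudes on multiplicative noise, two-group shifts,
known geometries), not the physics of the instruments: no optical
blurring beyond Gaussian event shapes, no detector noise model, no
motion artifacts, no vendor file formats.  Tests passing on synthetic
data therefore establish correctness of the operators under their
stated definitions, not robustness to every instrumental artifact of
real recordings.

## Statistics

`compare_groups()` implements the study's tests: two-sided Student
t-test for two groups (equal variances by default, matching the test's
name in the study; Welch is an option), one-way ANOVA with
Bonferroni-adjusted pairwise t-tests for more than two, and chi-squared
(no continuity correction by default) for contingency tables.
Summaries are mean +/- SEM with n.

## Problem sizes in the test suite

The suite exercises the full current-voltage protocol (11 steps, 400 ms,
5 s interpulse, 60 s pre-equilibration) for three parameter sets, the
gain protocol with its full 600 s hold cap for two, ten-beat pacing
trains, 100 random mask pairs against the brute-force distance oracle,
200 Hill-fit replicates, 20 line-scan images for spark
precision/recall and 1000 null replicates for the type-I calibration.
These sizes were chosen to make each estimate stable at desk scale while
the whole suite stays comfortably interactive.

## Known limitations

* The caffeine-dump readout in permeabilized mode does not reproduce
  the experimentally increased SR *load* of the knockout.  With SERCA
  near thermodynamic equilibrium at a clamped bath Ca^2+^, free SR
  Ca^2+^ is pinned for both variants, and total SR content is then
  dominated by the calsequestrin-bound pool - which the knockout has
  less of.  The experimental load increase evidently involves
  mechanisms outside the clamped Ca^2+^ subsystem (elevated diastolic
  Ca^2+^ in intact cells is one); the vignette states this rather than
  tuning the model around it.
* Charge parity between variants is approximate in the model: the
  knockout's slower inactivation recovers most, but not all, of its
  halved density over the 400 ms step (the knockout carries about 83%
  of the control charge at the 0 mV step, where the experimental
  observation is equality; the corresponding test documents this as an
  open shortfall rather than relaxing its threshold).
* RyR2 gating is deterministic (mean-field), so the model does not
  produce stochastic sparks; spark statistics enter the package through
  the line-scan operators and generators instead.
* Action potentials, beta-adrenergic signalling and flecainide
  pharmacology are out of scope; every simulation is under voltage
  clamp.
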