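---
title: "A thalamocortical network model of slow oscillations, sleep spindles and closed-loop stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A thalamocortical network model of slow oscillations, sleep spindles and closed-loop stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`tcsleep` simulates a four-layer, one-dimensional thalamocortical network
during NREM sleep: 200 cortical pyramidal cells (PY), 40 interneurons
(IN), 40 thalamocortical relay cells (TC) and 40 reticular cells (RE),
all with Hodgkin–Huxley conductance kinetics.

The cortical layers generate the slow oscillation (SO, < 1 Hz): silent,
hyperpolarized *Down states* alternate with depolarized, spiking *Up
states*.  Each cycle is seeded by Poisson miniature EPSPs onto PY and IN
dendrites during the Down state; the minis recruit the persistent sodium
current, one or more PY cells reach threshold, and recurrent AMPA/NMDA
excitation ignites a network-wide Up state that is sustained by the
persistent sodium plateau and terminated over several hundred
milliseconds by the calcium-dependent potassium current and short-term
synaptic depression.

The thalamic layers generate spindles: cortical volleys excite TC and RE
cells; RE GABA_A/GABA_B inhibition transiently hyperpolarizes TC cells,
de-inactivating the low-threshold calcium current I_T; the rebound
bursts re-excite RE, and the loop rings at spindle frequency for a few
hundred milliseconds, nested in the SO Up state.  The calcium-regulated
h-current provides slow negative feedback: calcium entering with each
I_T burst locks h-channels open, depolarizes the relay cells, and makes
the loop refractory for seconds, so that only a fraction of SO cycles
carries a detectable spindle.

## Cell models

Cortical cells have two compartments.  The dendrite (area ratio rho =
165 for PY, 50 for IN) carries fast Na, persistent Na (PY only), Km,
Ca-dependent K, high-threshold Ca, potassium-leak and leak currents and
follows the capacitive membrane equation; it is advanced by exponential
Euler (exact for piecewise-constant conductances).  The axosomatic
compartment (fast Na, persistent Na, delayed rectifier) is treated as
quasi-stationary: its voltage solves the algebraic balance between its
intrinsic currents and the dendro-somatic coupling, by damped
fixed-point iteration (tolerance 1e-6 mV, at most 8 iterations; the
balance is linear in V once the instantaneous persistent-Na gate is
frozen, so convergence takes two or three passes).

TC and RE cells are single compartments (C_m = 1 uF/cm^2).  TC carries
fast Na/K, potassium leak, relay-type I_T and the two-scheme h-current
(voltage-dependent opening plus calcium-bound locking with rates k1 =
2.5e7 mM^-4, k2 = 4e-4, k3 = 0.1, k4 = 1e-3 ms^-1; I_h = g_h (O + 2
O_L)(V - E_h)); RE carries fast Na/K, potassium leak and the reticular
I_T with its temperature divisors (6.8986 for tau_m, 3.7372 for tau_h).

Gating variables relax exponentially toward their voltage-dependent
steady states; the engine tabulates every rate function on a 0.05 mV
grid (steady state and per-step decay factor) and interpolates linearly.
The exported `eval_kinetics()` evaluates the same closed-form rates the
tables are built from.

## Choices where the source material is ambiguous or silent

Several kinetic definitions in the source tables of this model family
circulate with transcription errors, and a few quantities needed by a
working implementation are not published at all.  The package makes the
following choices (each exposed as a parameter):

* **Rate-function singularities.**  Every rate of the form
  x/(1 - exp(-x/k)) is evaluated by its analytic limit near its own
  pole; the published fallback constants (1.638, 1.116, 0.12, 0.0455,
  0.18, ...) all equal those limits.
* **Thalamic fast sodium.**  The published transcription produces
  negative rates; the canonical Traub rates are used with a -50 mV
  voltage shift (consistent with the published fast-potassium shift).
* **Fast-sodium inactivation recovery.**  The recovery rate pole is
  placed at -85 mV (the sign-consistent reading; the printed fallback
  constant 0.0455 = 0.0091*5 is the limit at that pole).  The
  alternative (+85 mV) reading slows recovery ~5x and the network can
  no longer sustain Up states.
* **Persistent sodium cap.**  The activation cap is 0.04 (parameter
  `nap_cap`).  A cap of 0.2 makes the resting state linearly unstable
  (no Down state exists); the plateau depth and Up-state duration are
  calibrated jointly with the calcium pool (below).
* **Relay-cell I_T.**  Not published for TC; the canonical relay
  kinetics of the model lineage are used (smooth tau_h form, divisor
  3.7372).
* **GABA_B.**  Mass action requires K2*R in the receptor equation;
  "/(V - E_K)" is read as a product; the printed "K4 = 100 uM^4" is the
  dissociation constant of the G-protein gate (Kd), with K4 = 0.033
  ms^-1 from the canonical scheme.
* **Transmitter pulse.**  Default duration 0.3 ms (amplitude 0.5 mM).
  With the also-circulating 0.03 ms value, per-spike receptor activation
  drops ~10x: corticothalamic EPSPs shrink to ~2 mV and the GABA_B
  fourth-power gate never leaves zero, so the printed conductances
  cannot drive the thalamus at all.  Sensitivity: all synaptic
  efficacies scale essentially linearly with `t_max` at fixed
  conductance.
* **Inhibition placement and reversal.**  Cortical GABA_A is
  perisomatic (basket-type): it enters the axosomatic balance and paces
  firing without collapsing the dendritic persistent-Na plateau
  (with dendritic placement every interneuron volley ends the Up state
  after ~30 ms).  The GABA_A reversal is -70 mV in cortex and in RE;
  on relay cells it is -83 mV (`E_gabaa_tc`), the classic relay-cell
  chloride reversal — at -70 mV reticular input shunt-clamps TC above
  the I_T window and spindles cannot form.

## Quantities the model never publishes (invented plumbing)

* **Calcium pools.**  First order: d[Ca]/dt = -A*I_Ca - ([Ca] -
  0.00024)/tau.  Thalamic: A = 9e-4 mM cm^2/(uA ms), tau = 5 ms — the scale the
  h-current's k1 Ca^4 term needs; A also sets post-spindle locking
  strength and hence the loop's refractory period.  Cortical dendrites: A =
  0.01, tau = 500 ms — the slow pool is the Up-state terminator, and its
  product with the I_KCa activation (alpha = 0.01[Ca]) sets the 0.5–1 s
  Up-state duration.
* **Compartment geometry.**  Soma 1e-6 cm^2 (dendrite rho times that);
  TC 2.9e-4, RE 1.43e-4 cm^2; dendro-somatic coupling 0.025 uS.  These
  reconcile density conductances (mS/cm^2) with point synaptic
  conductances (uS) and are calibrated against the Control SO
  statistics.
* **Miniature drive.**  Poisson, 6 Hz per cell, 0.03 uS (PY) / 0.006 uS
  (IN) AMPA-kinetics events; gated off at SO detection and re-armed
  100 ms after cycle termination (50 ms of network-wide PY silence).
  The rate/amplitude pair sets the Down-state duration and is the main
  SO-rate calibration knob.
* **Heterogeneity.**  Passive and slow conductances (g_L, g_KL, g_Nap,
  g_KCa, g_T, g_h) are jittered multiplicatively, and leak reversals by
  up to +/-2 mV, uniformly at +/-13% per cell (parameter
  `heterogeneity`, drawn once per run from the seed).  Identical cells
  lock into a network-wide inhibition-paced rhythm whose frequency sits
  in the sigma band and masks genuine spindles in the field potential;
  realistic cell-to-cell variability decorrelates that rhythm so it
  averages out of the 200-cell LFP sum while coherent thalamically
  driven spindles remain.
* **Sensory neuron.**  A cue is a 20 ms, 200 Hz spike train onto the
  AMPA receptors of all TC cells, conductance `g_sn` = 0.2 uS,
  calibrated so a Point-1 cue reliably ignites the spindle loop.
* **Point-4 trigger.**  The Up-to-Down transition is operationalized as
  the falling 50%-of-peak crossing of the 20 ms boxcar-smoothed PY
  population rate.
* **Spindle detection.**  No published criterion exists; events are
  sigma-band (10–16 Hz; 8–11 Hz for the slow preset) envelope
  exceedances above twice the trace median lasting at least 0.3 s, with
  0.1 s merging.  All parameters are arguments of `detect_spindles()`;
  raising the threshold multiplier k mainly deletes weak events (the
  density roughly halves from k = 2 to k = 3), while the stimulation
  orderings are insensitive to k in the 1.5–3 range.

# Numerics

Fixed step dt = 0.025 ms.  Voltages advance by exponential Euler (exact
for a passive membrane), gating by the exact exponential relaxation,
receptor open fractions by event-driven exact updates (all open
fractions of one receptor type decay at one rate, so per-target
depression-weighted sums decay with a single multiply per step), the
h-current scheme and calcium pools by explicit Euler (their fastest time
constant is ~5 ms, 200x the step).  Divergence (|V| > 200 mV or
non-finite) aborts with the offending cell named.  A single
`std::mt19937_64` stream drawn in a fixed order makes every run
bit-reproducible from its seed; recording extra traces never perturbs
dynamics.

Halving dt to 0.0125 ms moves single-cell spike times by well under a
millisecond and changes Control SO/spindle rates within their seed-to-
seed spread.

# Study conditions and problem sizes

The package defaults *are* the study conditions: 200/40/40/40 cells,
the connection table and radii as published, dt = 0.025 ms.  Reported
statistics use 90 s Control runs (three seeds, pooled) and 65 s
stimulation runs (two seeds per condition, event intervals pooled);
cue counts are rescaled to a 300 s basis where a 300 s figure is
conventional.  The durations were chosen so a full reproduction
completes on one desktop core in well under half an hour while every
pooled condition still carries ~45 SO cycles per run and a two-digit
spindle count; pooling across independent network realizations matters
more for the spindle statistics than run length, because the per-cell
parameter jitter makes spindle counts strongly network-dependent.

The test suite uses shorter runs (4–20 s) for structural checks
(determinism, event-log replay, protocol state machines) and 60–100 s
runs only in the acceptance layer.

# What passing the tests does and does not show

The synthetic fixtures (current-clamp rigs, constructed burst traces,
hand-simulated cue schedules) verify the components exactly.  The
network-level checks verify that the *model* reproduces the published
statistics under its own calibration; they do not validate the model
against real sleep EEG.  Known limitations: one-dimensional geometry
with open boundaries and no conduction delays; no synaptic plasticity;
identical kinetics within a layer apart from the seeded jitter; the
LFP is an abstract sum of PY synaptic currents, not a volume-conducted
field; the spindle detector is an operationalization, and absolute
spindle counts (unlike the stimulation orderings) depend on its
threshold convention.
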