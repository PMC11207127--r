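# tcsleep

Conductance-based simulation of the thalamocortical system during NREM
sleep, for computational neuroscientists studying how closed-loop
sensory stimulation shapes sleep spindles.

The model is a four-layer, one-dimensional Hodgkin–Huxley network: 200
cortical pyramidal cells (PY) and 40 interneurons (IN) generate the
slow oscillation (SO, < 1 Hz alternation of silent Down states and
depolarized Up states), while 40 thalamocortical relay cells (TC) and
40 reticular cells (RE) generate sleep spindles (waxing-and-waning
10–16 Hz bursts) through their reciprocal AMPA/GABA loop, paced by the
low-threshold calcium current

    I_T = g_T m^2 h (V − E_Ca)

and the calcium-regulated h-current (open fraction O, calcium-locked
fraction O_L; I_h = g_h (O + 2 O_L)(V − E_h)).  Cortical cells are
two-compartment (dendrite + quasi-stationary axosomatic compartment);
each membrane current follows I = g m^M h^N (V − E) with the gating
equations dx/dt = −(x − x_inf(V))/tau_x(V).  Synapses are first-order
kinetic receptors (AMPA, NMDA, GABA_A) with short-term depression
D_{n+1} = 1 − (1 − D_n(1−U)) e^{−Δt/τ} on the intracortical
projections, plus a second-order G-protein GABA_B current
g [G]^4/([G]^4 + K_d)(V − E_K).

On top of the network sits an online SO detector (arm after > 100 ms of
network-wide PY silence, detect at the 75th spike: the Down-to-Up
transition) and three closed-loop protocols that deliver 20 ms sensory
cues to the TC layer through an AMPA pathway:

* **CLS** — cue two successive SOs, then pause detection 2.5 s;
* **sCLS** — pause after every single cue;
* **DSt** — cue every SO while Down states stay under 0.5 s, else pause.

Cues can be placed at the Down-to-Up transition (Point 1), 120/180 ms
later (Points 2/3), or at the Up-to-Down transition (Point 4).

## A worked example

```r
library(tcsleep)

cfg <- sim_config(duration_s = 100, seed = 2)   # Control, fast preset
rec <- run_simulation(cfg)
summary(rec)
```

```
100 s simulation
  slow oscillations : 28.80 /min
  spindles          : 3.60 /min
  inter-spindle     : 13.24 +/- 6.17 s
  stimulation cues  : 0
```

Around 30 slow-oscillation cycles per minute are detected online; the
sigma-band (10–16 Hz) envelope detector finds a spindle nested in
roughly one Up state in seven, a spindle density of a few per minute
with irregular ~12 s inter-spindle intervals.  Spindle counts are
strongly seed-dependent (per-run densities of 1–7/min are all typical);
the reproduction script below therefore pools several seeds.  A
closed-loop run stimulating every detected SO pair:

```r
stim <- run_simulation(sim_config(duration_s = 100, seed = 2,
                                  protocol = "cls", point = 1))
summary(stim)        # shorter inter-spindle intervals, more cues
plot(stim, t_lim = c(20, 35))   # raster + LFP with cue markers
```

Useful pieces on their own: `sim_current_clamp()` (single-cell rigs),
`eval_kinetics()`/`channel_registry()` (the intrinsic-current tables),
`detect_spindles()`, `welch_psd()`, `lfp_spectrogram()` (trace
analysis; they accept any uniformly sampled trace), and the protocol
replayers `so_detect()`, `cls_schedule()`, `dst_schedule()`.  A thin
command-line front-end lives in `exec/tcsleep`
(`run` / `analyze` / `dump-params`).

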