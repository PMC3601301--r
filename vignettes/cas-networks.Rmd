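---
title: "Center-annular-surround spiking networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Center-annular-surround spiking networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(casnet)
```

## The model

`casnet` simulates two-dimensional sheets of conductance-based spiking
neurons.  Each neuron follows the two-variable quadratic
integrate-and-fire dynamics

$$C\dot v = k\,(v - v_r)(v - v_t) - u - I_{syn} + I_{ext}, \qquad
  \dot u = a\,\{b\,(v - v_r) - u\},$$

with a peak-and-reset rule: when $v$ exceeds $v_{peak}$ the neuron emits a
spike, $v \leftarrow c$ and $u \leftarrow u + d$.  Membrane potential is in
mV, currents in pA, conductances in nS, time in ms.  Excitatory and
thalamic relay cells use the regular-spiking parameter set
($C=100$, $k=0.7$, $v_r=-60$, $v_t=-40$, $a=0.03$, $b=-2$, $c=-50$,
$d=100$, $v_{peak}=35$); inhibitory cells use a linearized fast-spiking
set ($C=20$, $k=1$, $v_r=-55$, $v_t=-40$, $a=0.2$, $b=2$, $c=-45$, $d=0$,
$v_{peak}=25$).  Every parameter can be overridden through
`neuron_params()`.

Synaptic input is carried by five receptor conductances — AMPA, NMDA,
GABA-A, GABA-B and a slow hyperpolarizing (SH) conductance — each decaying
exponentially with time constants 5, 150, 6, 150 and 5000 ms and reversal
potentials 0, 0, −70, −90 and −90 mV.  The NMDA term carries the standard
voltage-dependent magnesium-block factor
$[((v+80)/60)^2]/[1+((v+80)/60)^2]$, which vanishes exactly at −80 mV.
A presynaptic spike of an excitatory cell increments the target's AMPA
conductance by $x\,s$ and its NMDA conductance by
$\mathrm{nmda\_gain}\cdot x\,s$, where $s$ is the synaptic weight and $x$
the short-term plasticity factor; inhibitory spikes increment GABA-A,
GABA-B (scaled by `gabab_gain`) and SH (scaled by `gabash_gain`, zero in
all experiments except visuomotor learning, where it is 0.2 for the first
45 s).

Short-term plasticity follows a one-variable resource model: $x$ relaxes
exponentially to 1 with a pathway-specific time constant and is multiplied
by $p$ at every presynaptic spike ($p<1$ depression, $p>1$ facilitation).
The pathway table is: excitatory and inhibitory pathways 150 ms / 0.8;
thalamic→excitatory 150 ms / 0.7; thalamic→inhibitory 200 ms / 0.5.

Plastic pathways use spike-timing-dependent plasticity with an
eligibility trace: each pre/post pairing adds
$\alpha\,\mathrm{STDP}(\Delta t)$ to a per-synapse trace $c$ that decays
with $\tau_c = 1$ s; the window is $+A_+ e^{-\Delta t/20}$ for
pre-before-post and $-A_- e^{-|\Delta t|/20}$ otherwise, with $A_+=0.005$,
$A_-=0.001$.  Weights integrate the trace ($\dot s = c$) once every 50 ms,
and homeostatic synaptic scaling immediately renormalizes each neuron's
incoming sum on the pathway to its target total (clip to $[0, s_{max}]$,
multiplicative rescale, re-clip).

## Anatomy

Populations live on square grids that are registered onto the same
physical patch (2 mm × 2 mm by default), so a 59×59 excitatory sheet and a
30×30 inhibitory sheet have proportionally different spacings.  Four
wiring generators cover the studied architectures:

* local Gaussian (probability and initial weight fall off as a Gaussian of
  distance),
* annular surround (sources restricted to $r_{min} \le d \le r_{max}$,
  probability Gaussian around the annulus center),
* uniform random, and
* topographically limited random (uniform within a maximum retinotopic
  radius; used for thalamic input in the map and reach experiments).

Connection probabilities are rescaled so the expected in-degree matches a
target count; draws are independent Bernoulli per candidate pair, without
autapses or duplicates.  Boundaries are non-periodic: probability mass
falling outside the sheet is lost before rescaling, matching the visible
edge effects of patch-based simulations.  Initial weights are rescaled per
neuron so each cell's incoming sum equals the pathway's coupling total —
these totals ("couplings", in nS) are the primary experimental parameters.

The center-annular-surround (CAS) architecture wires excitatory axons
locally and inhibitory axons to an annular surround.  The three control
architectures are: classic center-surround (all Gaussian, inhibition
broader than excitation), inverse (excitation annular, inhibition local)
and uniform random.

## Numerical choices

The engine advances in 1-ms ticks.  Within a tick the membrane equation
takes two half-steps; the conductance current, which is linear in $v$ and
can be arbitrarily stiff at strong coupling (the effective membrane time
constant $C/g$ drops below the step), is treated semi-implicitly inside
each half-step while the quadratic intrinsic term stays explicit.  A fully
explicit step destabilizes at a few hundred nS of total conductance and
produces spurious tick-locked firing; the semi-implicit form is
unconditionally stable in the synaptic term and agrees with a
$dt=0.01$ ms reference integration to within 5% in firing rate.  Spikes
take effect on the following tick; no axonal delays are modeled.  Each
neuron can fire at most once per tick, which rate-limits the fast-spiking
class above ~300 Hz: refinement convergence (halving $dt$) is exact to
±1 spike for the regular-spiking sets at moderate drive, while
fast-spiking cells driven to few-ms intervals shift by tens of percent.
This is inherent to 1-ms integration of fast interneurons and is the
reason the package's quantitative claims are made on excitatory activity.

Spike delivery uses the short-term plasticity factor before its
spike-triggered reset (resources are consumed by the spike that uses
them).  Same-tick pre/post spike pairs are paired against the partner's
previous spike, never at $\Delta t = 0$.  The eligibility trace decays at
the 50-ms application cadence with the exact factor $e^{-0.05}$, so pure
decay over 1 s equals $e^{-1}$ exactly; increments are not fractionally
decayed within a cadence interval (at most a few percent timing error,
and a large speed gain on all-to-all plastic pathways).  Initial
conditions: $v=-60$ mV everywhere, $u$ uniform on 0–100 pA, conductances
zero, $x=1$, traces zero.  All randomness (wiring, initial state,
stimuli) is drawn on the R side; the C++ engine is fully deterministic.

## Study conditions and how they were fixed

The quantitative parameter tables of the original study are not available,
so all structural and coupling values were fixed once by pilot search and
are recorded in `structure_defaults()`, `gain_defaults()`,
`sweep_defaults()`, `map_defaults()` and `reach_defaults()`:

* **Coupling sweep / WTA exemplar** (`run_sweep()`, `run_wta_exemplar()`):
  full-size sheets (59×59 excitatory, 30×30 inhibitory, 484 thalamic),
  local σ 0.2 mm, annulus 0.3–2.9 mm (σ 0.8) — the surround spans the
  rest of the sheet, giving global competition — in-degrees 50/50/20,
  NMDA/AMPA gain 0.2, GABA-B/GABA-A gain 0.05, fixed couplings
  `ee = 400`, `te = 80`, `ti = 15` nS, and the constraint
  `ii = 2.4 × ie`.  Thalamic input is a fixed random half-on pattern whose
  amplitude is calibrated by bisection to a ~100 Hz peak rate
  (`calibrate_input_current()`).  The sweep spans `ei` 50–400 and `ie`
  10–2500 nS, bracketing the transition from the epileptic corner (low
  inhibition, nearly every neuron firing) to the WTA region; the exemplar
  sits at `ei = 400`, `ie = 2500`.  Simulations run 3 s and the third
  second is measured, by which time the dynamics have settled.
* **Orientation maps** (`train_orientation_map()`): a desk-scale 20×20/
  10×10 sheet with topographic thalamic input (0.65 mm radius), an
  input-dominated regime (`ee = 50`, `te = 150`, local annulus
  0.3–0.7 mm) in which activity tracks the stimulus position, plastic
  thalamic→excitatory synapses (α = 80, per-synapse cap at 12% of the
  incoming total so receptive fields keep several strong inputs), 200
  elongated Gaussian stimuli × 3 repetitions × 500 ms (300 simulated
  seconds; the full-scale protocol of 60×60 neurons and 40 000 s runs the
  identical loop), and the annealed inhibition ramp: the GABA conductance
  onto excitatory cells rises linearly from zero to its plateau over the
  first quarter of training.
* **Visuomotor reaching** (`reach_experiment()`): reduced visual and motor
  sheets (20×20 + 10×10 each).  The visual sheet is parameterized as a
  near-linear topographic relay (`ee = 20`, weak inhibition) so its
  activity is roughly proportional to image brightness — a WTA-regime
  visual sheet produces nearly identical responses for all targets and
  nothing can be learned.  The motor sheet has a predetermined map of
  preferred joint angles; population-vector decoding (rate-weighted mean
  of preferred angles, previous posture held at zero rate) commands a
  planar two-joint arm every 250 ms.  Training injects current into one of
  nine motor spots for 450 ms (15 repetitions), with an additional decode
  100 ms after onset, mirroring the fast open-loop settling of the
  stimulated patch, and 300-ms inter-trial blanks so the previous winner
  dies out.  The camera frame is fitted to the workspace of the central
  60% of the joint ranges (population-vector commands cannot reach the
  extremes).  The slow hyperpolarizing receptor is active (gain 0.2) for
  the first 45 s, then off.  Testing freezes plasticity, turns motor
  stimulation off, renders the target blob at the nine trained locations
  and records the settled decoded posture.

## What the synthetic data emulate — and what they do not

Thalamic "images", oriented Gaussian bars and the arm's camera view are
idealized: noise-free, perfectly calibrated and stationary.  Real video
input would add luminance noise, occlusion and temporal correlations none
of which are modeled.  Passing the package's tests therefore shows that
the architecture and plasticity rules produce the claimed phenomena under
clean driving conditions; it does not certify robustness to real sensors.

## Known limitations

* The Willmore–Tolhurst sparseness of a winner-take-all state and the
  fraction of neurons with elevated rates trade off sharply in this model
  family: with quadratic integrate-and-fire cells there is no stable
  firing below ~15–20 Hz under tonic drive, so winning patches lack a
  wide low-rate halo and sparseness above 0.9 empirically caps the
  ≥2 Hz active fraction near 15–18% (an extensive search over annulus
  geometry, receptor gains, adaptation strength and drive is summarized
  in the package sources).  The exemplar was fixed at the operating point
  that robustly satisfies the WTA-regime properties.
* Control architectures acquire moderate sparseness (0.4–0.7) at the
  strong-inhibition end of the sweep through partial silencing, and the
  recurrence strength the CAS winners need also skews firing in the
  controls; the regime ordering in which controls stay quasi-uniform
  across the entire swept range was not reproducible without the original
  coupling tables.
* At desk scale, untrained orientation maps are also smoother than the
  permutation null, because winner patches respond as units and
  neighboring cells share thalamic afferents; the trained-map smoothness
  test is therefore necessary but not specific to learning.
* In the reduced reaching experiment the visually evoked postures cluster
  near the workspace center: the motor sheet's intrinsic winner bias under
  weak visuomotor drive exceeds the learned drive contrast, so
  target-specific reaching is only weakly expressed even though the
  pooled joint errors stay well inside the reported bound and beat the
  no-learning ablation.

## Reproducing the numbers

`scripts/acceptance.R --seed N --out results.json` recomputes the
headline quantities end to end: the exemplar's active fraction (5 seeds),
the three control architectures' sparseness maxima over the 8×8 coupling
sweep, and the pooled maximum joint error of the reaching experiment
(5 seeds).  The testthat suite runs the same experiments at the same or
smaller scales.
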