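---
title: "Modelling extrinsic and intrinsic theta sequences in CA3-DG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling extrinsic and intrinsic theta sequences in CA3-DG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`thetanet` simulates a spiking network of hippocampal place cells in a
square open field and the analyses used to characterise theta-timescale
spike sequences. Two mechanisms generate sequential firing within a ~100-ms
theta cycle:

* **Extrinsic sequences** follow the animal's current movement. Recurrent
  CA3 collaterals are symmetric in space, but short-term synaptic
  depression (STD) of the CA3 presynaptic resource `s_D` depletes the
  synapses of recently active (i.e. behind-the-animal) cells, so recurrent
  drive reaches forward and the within-cycle firing order follows the
  running direction.
* **Intrinsic sequences** follow a hard-wired CA3 -> DG -> CA3 loop. DG
  place cells mirror the CA3 population; their projections back to CA3
  target cells displaced 4 cm along a fixed direction `theta_dg`, so loop
  activity replays the same spatial order regardless of how the animal
  moves. A path gate (`loop_path_gain()`) confines the loop to a 40-cm
  band, and loop weights favour cell pairs with similar preferred heading
  directions.

Each of the 6400 CA3 and 1600 DG cells is an Izhikevich neuron with burst
parameters `(a, b, c, d) = (0.035, 0.2, -60, 8)`; two populations of 250
fast-spiking interneurons `(0.02, 0.25, -65, 2)` provide all-to-all
feedback inhibition per layer. Synapses are conductance-based with
reversal potentials 0 / -80 mV, decay constants 12 / 10 ms and a 2-ms
transmission delay. Every neuron is inhibited by a subtracted theta drive
`7 (1 + cos(2 pi t / 100 ms)) / 2`; CA3 cells additionally receive box
place-field input (5 cm radius) with a directional gain
`A_pos + A_dir exp(cos(psi - psi_i) - 1)`, gated by a theta-modulated
entorhinal envelope peaking 70 degrees after the theta peak, and subject
to short-term facilitation (STF) whose squared resource multiplies the
drive.

## Parameters

Parameter presets (one per simulated condition, `preset_names()`) collect
the published operating points: sensory amplitudes `A_pos`/`A_dir`, STF
constants `S0F`, `S1F`, `Phi_F`, CA3 weight scales `B_pos`, `B_dir`,
`K_CA3`, the STD fraction `U_D`, DG loop scales `B_DG`, `K_DG`, and the
four inhibitory weight maxima. The parameter table we transcribed collapses
runs of equal values across conditions, leaving a few cells ambiguous; the
presets encode one consistent reading (documented in `R/config.R`), chosen
so that each condition is a minimal change from its neighbours and so that
the published summary statistics are reproduced, and **every scalar can be
overridden** through `network_config()` so any other reading is one
argument away.

Three modelling questions were genuinely open and are resolved as follows
(each has a config switch):

* `theta_to_inhibitory = FALSE`: the oscillatory drive reaches place cells
  only. A fast-spiking Izhikevich cell under the rhythmic drive fires a
  rebound spike every cycle with no synaptic input at all, and that
  spontaneous synchronized inhibition silences the weakly driven
  single-layer conditions entirely; routing theta to place cells only
  keeps the interneurons purely feedback devices.
* `std_mode = "subtractive"`: the printed resource dynamics
  `ds/dt = (1 - s)/tau_D - U_D delta(t - t_f)` integrate across a spike to
  `s - U_D`, clamped at zero. A multiplicative variant `s (1 - U_D)` is
  available; the subtractive rule restricts effective release to the
  freshest (leading-edge) cells and is what reproduces the published
  extrinsic precession slope.
* `std_to_dg = TRUE`: depression applies to every synapse with a CA3
  presynaptic cell, including the loop afferents (strict reading). With
  `FALSE` the loop fires roughly six-fold more but its added spikes
  decorrelate the pairwise lag structure.

The release coefficient of a delivered spike is `s_D` evaluated at arrival
time (`std_release = "delivery"`, as the printed conductance equation
states); an emission-time variant is available but degrades the
direction-flip signature of extrinsic correlations.

## Numerics

The membrane equations advance by forward Euler at `dt = 0.1` ms, with one
deliberate exception: the synaptic conductance terms are folded in
semi-implicitly,

```
v_new = (v* + dt (g_E V_E + g_I V_I)) / (1 + dt (g_E + g_I)),
```

where `v*` carries the intrinsic quadratic and stimulus terms explicitly.
A pure explicit step overshoots far below the inhibitory reversal whenever
`g_I dt` is large (a single step with `g_I = 20` throws `v` from -60 to
about -100 mV); the artificially deep hyperpolarisation drags the recovery
variable down and the bursting cells then fire synchronized rebound bursts
that destabilise the whole network. The semi-implicit form keeps the
synaptic pull bounded by the reversal potentials at any conductance, costs
one division, and leaves weak-conductance behaviour identical to Euler.
Halving `dt` changes the total CA3 spike count of a standard run by about
0.1%.

Neurons start at their type-specific resting fixed point (`-70` mV
excitatory, `-64.4` mV inhibitory); starting both types at `-70` mV makes
every interneuron fire one spurious start-up spike because the
fast-spiking parameters have no stable rest below about -64 mV.

Spike times are recorded at the end of the step in which `v` crosses
30 mV from below, and delivered exactly 2 ms later.

## Analyses

* `spike_phase()` maps times to `[0, 2 pi)` with phase 0 at the theta-drive
  maxima.
* `fit_precession()` is a circular-linear regression: the slope maximises
  the mean resultant length of `phase - a x` over `|a| <= 4 pi` per
  normalised traversal (coarse grid at 1e-3 of the range plus
  golden-section refinement); positions are normalised so the first/last
  spike map to 0/1. Cells need more than 5 spikes (the activity filter
  used throughout).
* `cross_correlogram()` bins spike-pair lags at 5 ms over +-100 ms. The
  pipeline references each pair to its *first-encountered* cell per run
  and bins `t_first - t_next`, the orientation under which a sequence
  played out in running order gives a positive correlation-lag phase and
  a loop opposing the run adds counts at positive lags.
* `correlation_lag()` band-passes the histogram at 4-12 Hz (zero-phase
  second-order Butterworth applied in the frequency domain on a three-fold
  zero-padded signal -- the frequency-domain equivalent of a
  forward-backward filter) and returns the analytic-signal phase at zero
  lag, interpolated between the two bracketing bin centres.
* `ex_in()` rescales Pearson correlations between the two runs'
  histograms: extrinsicity compares them directly, intrinsicity after
  time-flipping the reverse-run histogram; a pair is extrinsic iff
  `Ex > In`. Overlapping pairs are field centres closer than 10 cm (two
  box radii); the averaged correlograms of `averaged_correlogram()` use
  pairs separated by 4 +- 0.5 cm along the running direction.
* `theta_compression()` regresses correlation-lag phase on centre distance
  (Euclidean by default) over `|a| <= 0.5` rad/cm.
* `gradient_map()` summarises one cycle as arrows toward later-spiking
  lattice neighbours (arithmetic mean spike times within the window).
* The tempotron (`tempotron_*()`) uses the double-exponential kernel with
  `tau = 5`, `tau_r = 1.25` ms normalised to unit peak, threshold 2,
  learning rate 0.01, and only-(+)-pattern training: silent patterns
  potentiate every afferent spiking before the un-shunted voltage maximum.
  For an identically flat trace (zero initial weights) the credit window
  is taken from the unit-weight trace, the limit of vanishing equal
  weights. Jittered spikes stay assigned to their original cycle.

## What the simulations do and do not show

The scenario runner (`run_scenario()`) reproduces the study conditions:
2-s, 20-cm/s straight traversals of an 80 x 80 cm arena (bidirectional for
the correlation analyses), loop directions 0/45/90/180/225/270 degrees, a
DG lesion (loop silenced, facilitation replaced by raised constant
release), a no-CA3-recurrence variant, stationary-stimulus training of
tempotron readouts at a loop and a non-loop location with 24 test
directions, and single-cycle gradient maps. These are synthetic
conditions: straight runs at constant speed, box-shaped fields on a
perfect lattice, and semi-randomised preferred directions. Passing tests
demonstrate the mechanisms' internal consistency at the published
operating point, not behaviour under natural foraging trajectories,
irregular field shapes, or learned (plastic) loop connectivity.

Under the final configuration the package reproduces: the
direction-invariance of intrinsic correlograms versus the sign flip of
extrinsic ones, the extrinsic-model precession slope (~-0.85 rad per field
size, published -1.13 +- 0.4), the lower spike phases and onsets of
best-direction cells, all three extrinsicity orderings (best > worst,
dissimilar > similar, overall extrinsic majority), the control
theta-compression slope for a loop aligned with the run (+0.12 to +0.24
rad/cm depending on the wiring seed, published 0.183 +- 50%), and the
extrinsic-pair orientation along the running direction. Known quantitative departures, all traceable to the
balance between recurrent-sweep and sensory timing that the printed
parameters do not pin down: the compression slope for an opposing loop
stays weakly positive instead of turning negative, the lesioned model
compresses more strongly than published, intrinsically classified pairs
are dominated by symmetric near-perpendicular pairs rather than loop
pairs, and the no-loop tempotron generalises across directions instead of
failing.

## Problem sizes

The bundled analyses run the full 6400-cell network (one 2-s run is about
10-15 s of compute); the unit tests exercise the same code paths on a
100-cell lattice with correspondingly scaled weights, cross-checked
spike-for-spike against a pure-R reference integrator.
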