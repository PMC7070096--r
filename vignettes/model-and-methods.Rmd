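---
title: "A multicolumn PFC spiking model of information maintenance: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multicolumn PFC spiking model of information maintenance: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `pfcmaint`, the choices
made where the design was genuinely open, and what the synthetic
experiments do and do not show. It states no empirical numbers beyond what
the package's tests and `scripts/acceptance.R` compute at run time.

## The scientific question

Neocortical interneurons differ systematically in how far their axons
reach: chandelier cells (ChC) inhibit pyramidal cells within their own
layer ("local-layer", LL); bipolar and double-bouquet cells (BPC, DBC)
span layers within a column ("cross-layer", CL); large basket and
Martinotti cells (LBC, MC) reach across layers *and* across columns
("long-range", LR). The model asks what each range class contributes to
holding a briefly presented stimulus as persistent activity, by deleting
one class at a time from a prefrontal-cortex-like column and measuring
how well the stimulus can still be read back from the spiking 160 ms
later — and whether neighboring columns can compensate for a missing
class through their long-range projections.

## Neurons

Each of the 2000 cells per column is an adaptive exponential
integrate-and-fire (aEIF) neuron,

$$C_m \dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_{th})/\Delta_T} + I - w,
\qquad \tau_w \dot w = a (V - E_L) - w,$$

with the reset rule $V \to V_r$, $w \to w + b$ on a spike. The
exponential term diverges once $V$ escapes past $V_{th}$, so a spike is
*declared* when $V$ crosses the numerical ceiling
$V_{peak} = V_{th} + 5\,\Delta_T$ (configurable multiplier); the
exponential argument is clamped at $V_{peak}$ so the step never
overflows. Input $I$ is the sum of a constant background current (250 pA
for pyramidal cells, 200 pA for interneurons, standing in for
out-of-network synapses) and the synaptic current.

Per-cell-type constants live in `inst/extdata/neuron_params.tsv`. They
are the package's own parameterization: the source tables for this class
of PFC models report *means* of measured distributions, so thresholds
are additionally jittered per neuron, $V_{th} \sim N(\mu_{type},
\sigma^2)$ truncated at $\pm 3\sigma$, with $\sigma$ = `vth_sd_mV`
(default 3.8 mV). This cell-to-cell variability is what gives the
network a realistic noise floor: without it the deterministic network is
either perfectly silent or perfectly epileptic, with nothing in between.

Two parameter choices deserve emphasis:

* **Pyramidal cells carry a depolarizing spike afterpotential**
  (`b = -20 pA`, `tau_w = 200 ms`). With purely random connectivity and
  purely presynaptic short-term plasticity, *pattern-selective*
  persistent activity is impossible — a facilitated synapse is
  facilitated for every postsynaptic target alike, so nothing
  distinguishes a stimulated cell from its neighbor once the stimulus
  ends. The memory trace must live in the cell. A negative $b$ is the
  aEIF idiom for an activity-dependent depolarizing aftercurrent (as
  described for prefrontal and entorhinal pyramidal cells): a cell that
  fired a burst keeps an inward current for a few hundred milliseconds
  and therefore keeps firing, while a cell that fired once or not at all
  relaxes back. Roughly two spikes within a stimulus window latch a
  cell; one stray spike does not. The aftercurrent saturates (`w_min_pA`,
  default -80 pA), as a finite ADP conductance must: without the floor a
  latched cell's firing rate has no stable ceiling. Large basket cells
  share the pyramidal parameter set (their electrophysiology is PC-like),
  so they latch too, which makes the long-range brake tonic rather than
  purely reactive.
* **Martinotti cells adapt slowly and cumulatively**
  (`b = +14 pA`, `tau_w = 600 ms`, threshold 2 mV below the other
  interneurons). They are the excitable, fatigable component of the
  inhibitory brake: strong early in a protocol, progressively slower
  across repeated stimulations. This is what turns the chandelier
  ablation from a mild single-stimulus deficit into a collapse under
  repeated stimulation.

## Synapses

Excitatory cells transmit through AMPA and NMDA, interneurons through
GABA$_A$. A presynaptic spike at $t_{sp}$ contributes a double-exponential
conductance transient after an axonal delay $\tau_D$ (default 1 ms), and
the NMDA conductance is additionally gated by the postsynaptic voltage,

$$s(V) = \frac{1.08}{1 + 0.19\, e^{-0.064 V}},$$

the standard magnesium-block sigmoid; AMPA and GABA$_A$ are ungated.
Receptor kinetics (onset/offset time constants, reversal potentials) are
in `inst/extdata/receptors.tsv`. The engine integrates each kernel as two
auxiliary first-order states per receptor per neuron, which is
algebraically identical to the explicit spike sum; the equivalence is
asserted against an explicit-kernel reference implementation in the test
suite.

Every connection carries Tsodyks–Markram short-term plasticity with
utilization $u$ (facilitation) and resources $R$ (depression):

$$a_n = u_n R_n, \qquad
u_{n+1} = u_n e^{-\Delta t/\tau_{facil}} + U(1 - u_n e^{-\Delta t/\tau_{facil}}), \qquad
R_{n+1} = R_n (1 - u_{n+1}) e^{-\Delta t/\tau_{rec}} + 1 - e^{-\Delta t/\tau_{rec}}.$$

The default triple is $U = 0.25$, $\tau_{facil} = 500$ ms,
$\tau_{rec} = 200$ ms. The source text and its printed recursion disagree
on the initial resource value ($R_1 = 1$ in the text vs. $R_1 = 1 - U$ in
the recursion base); the package follows the explicit textual statement
($u_1 = U$, $R_1 = 1$, so the first spike has efficacy $U$) and exposes
the alternative behind the `stp_r1_complement` option. AMPA and NMDA
conductances of the same excitatory connection share one release process
and hence one STP state. Per-connection overrides of the STP triple are
supported in the connectivity table; the package uses them for the
long-range inhibitory synapses (LBC/MC onto PC), which are given
low-utilization, slowly recovering depression so that the long-range
brake weakens cumulatively under sustained load — the synaptic half of
the fatigue mechanism described above.

## Network architecture

A column has two laminar compartments (L2/3, L5) and exactly 2000
neurons, allocated to (type, layer) populations by largest-remainder
rounding of the proportion table. The proportions are anchored to the
printed constraints: 900 L2/3 pyramidal cells (the stimulus grid maps
onto them one-to-one), a 75% excitatory share, a 4.1% CL share, and no
BPC population in L5. Every ordered cell pair is wired independently
with its rule's probability (one Bernoulli draw per pair — no autapses,
no multapses). Chandelier cells project only to pyramidal cells of their
own layer and column; CL cells project within their column across
layers; pyramidal and LR cells project across layers, and they are the
only types whose axons cross columns. Cross-column rules mirror the
within-column target preferences at configurable scale factors, separate
for excitatory and inhibitory projections (defaults 0.1 and 1.0: the
model treats inter-column excitation as sparse relative to the
long-range inhibitory plexus; the compensation phenomenon requires
cross-column inhibition to dominate cross-column excitation, and the
factors are explicit sensitivity knobs). Derived inhibitory cross-rules
are additionally normalized by the number of neighbor columns, so the
total cross-column inhibitory in-degree of a cell does not grow with the
stack size — without this, three neighbors silence a column outright.

Ablation is structural: the targeted class (e.g. `"LL:L23"`) is removed
from the built network together with every synapse touching it, before
simulation. All remaining rows are bit-identical to the intact network,
which makes ablated/intact comparisons exactly seed-paired.

## Stimulation, readout, accuracy

A stimulus is a binary 30×30 image (the standard one is a filled,
centered, apex-up triangle; random Bernoulli images are also available).
Cell $(i, j)$ of the image maps row-major onto the first 900 L2/3
pyramidal cells of a column. During each 20 ms stimulation window every
active cell's PC receives a deterministic 1000 Hz train (20 spikes, 1 ms
apart) through a dedicated AMPA stimulation synapse without STP. The
default stimulation conductance (28 nS) is set well above the minimal
calibrated value so that a window reliably drives stimulated cells into
the latched regime even under full inhibition; `calibrate_stimulus_weight()`
implements the minimal-weight sweep for users who want the threshold
itself.

Protocols: (a) one window at 51 ms; (b) five windows at 51, 301, 551,
801, 1051 ms; (c) protocol b replicated to every column of a 2–4 column
network. Each window is followed by a 160 ms readout anchored at the
stimulus offset (70–230 ms for protocol a). The readout image has a 1
wherever the mapped PC spiked at least once strictly inside the window,
and the accuracy statistic is the percentage of the 900 cells on which
input and output agree (joint silence counts as agreement). Experiments
are repeated 15 times; repeats redraw the connectivity realization and
the threshold jitter (the model has no other stochasticity under the
deterministic stimulus), and conditions within a study share seeds so
that differences are not confounded by realization noise. Means are
reported with the standard error of the mean across the 15 repeats. For
multicolumn runs every column is decoded against its own copy of the
input and the per-column accuracies are averaged (per-column values are
available in the reports).

## Numerical scheme

Explicit Euler at `dt = 0.05 ms` (configurable; the invariant tests also
run at finer steps). Within a step the order is fixed: deliver delayed
spikes (STP efficacy frozen at emission) and stimulus events → compute
synaptic and background currents → update all neuron states → detect
`V_peak` crossings, reset, and enqueue outgoing spikes at `t + tau_D`.
This order is part of the contract because it affects spike timing at
`dt` resolution. Everything is deterministic given (network, stimulus,
config) — rasters are reproducible bitwise. Spike delivery uses per-step
ring-buffer queues; delays are rounded to whole steps.

## Calibration of the default parameter tables

The connection-probability matrix and per-type parameter values of the
original model are not available to this package; the shipped defaults
were constructed to satisfy every printed constraint and then calibrated
— once, on the intact network — so that the model operates in the regime
the experiments describe: a quiet baseline with sparse heterogeneous
background activity, reliable latching of stimulated cells, a noise
floor of order a hundred misclassified cells in the intact column,
graded (not all-or-none) degradation under single ablations, cumulative
collapse of the chandelier-ablated column under repeated stimulation
with epileptiform persistent firing, and recovery of the collapse when a
second column's long-range projections are present. The calibration
logic is described above (latching threshold, brake shares, fatigue time
constants); the resulting numbers are in `inst/extdata/`. Because the
parameter tables are authored rather than transcribed, quantitative
agreement with the original accuracies is approximate by construction;
the acceptance suite asserts the ordering relations exactly and the
accuracy levels within a ±10 percentage-point band.

## Problem sizes used by the tests and acceptance script

The packaged experiments run the full 2000-neuron column (8000 neurons
for the 4-column condition) at the protocol durations (230 ms for
protocol a, 1230 ms for b/c) with 15 repeats per condition — the study's
own design — while structural/statistical unit tests use scaled-down
columns (150–400 neurons) where only wiring statistics, not dynamics,
are at stake.

## What the synthetic experiments do and do not show

The generator emulates the study conditions: binary images on a fixed
grid, deterministic high-rate stimulation, connectivity redrawn per
repeat. It does not emulate in-vivo background noise (the model's noise
is quenched heterogeneity, not ongoing stochastic input), distance-
dependent connectivity, layer 4, conductance noise, or neuromodulation.
Passing tests therefore show that the implemented circuit mechanisms are
sufficient to reproduce the ablation phenomenology under the stated
idealizations — not that cortical tissue realizes them this way.

## Known limitations

* The per-cell maintenance trace is not a fixed point: with the
  saturating aftercurrent, a stimulated cell's elevated firing decays
  over roughly 50–150 ms rather than lasting indefinitely. The readout
  scores a spike anywhere inside the 160 ms window, so window-level
  accuracy is high while the instantaneous representation fades toward
  the end of the window; repeated stimulation refreshes it.

* The intermediate states near the containment boundary are sensitive to
  the connectivity realization (the large trial-to-trial spread of the
  long-range-ablated condition is a property of the regime, not a bug).
* Delays are uniform by default (1 ms); the per-connection column exists
  but no distance model fills it.
* Readout windows anchored at stimulus offset are a convention; the
  source describes stimulation and readout as disjoint phases without
  fixing the anchor.
* `R_1 = 1 - U` initialization is implemented but untuned; switching it
  rescales every first-spike efficacy by $1-U$ and would require
  re-calibrating conductances.
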