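---
title: "Learning noisy spike-pattern episodes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning noisy spike-pattern episodes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`episodenet` simulates a recurrent network of conductance-based Izhikevich
neurons that learns spatiotemporal spike-pattern episodes from noisy,
incomplete presentations, the way hippocampal-like recurrent circuits are
thought to learn and prospectively recall sequences. Three mechanisms
interact:

* **Neuron dynamics.** Each neuron follows the hybrid Izhikevich model,
  either the nine-parameter quadratic form
  $C\,v' = k (v-v_r)(v-v_t) - u + I_{syn} + I_{noise}$,
  $u' = a(b(v-v_r) - u)$, or the classic four-parameter form
  $C\,v' = 0.04v^2 + 5v + 140 - u + I_{syn} + I_{noise}$ with a
  capacitance-like divisor $C$. When the Euler update carries $v$ past the
  cutoff $v_p$, the spike is stamped at the end-of-step boundary and the
  reset $v \leftarrow c$, $u \leftarrow u + d$ is applied within the same
  step (a hybrid scheme; no sub-step spike-time interpolation). The default
  step is $dt = 0.5$ ms; `integrate_step()` at this resolution agrees with
  a 0.01 ms reference on spike counts to within one spike per second over
  the model's operating drive range (up to ~100 pA; rheobase is ~32 pA)
  and within a few percent under sustained strong drive, where the
  above-threshold reset ($c = -40 > v_t = -45$ mV) makes the limit-cycle
  period sensitive to the integration step. Both bounds are asserted in
  the tests.

* **Conductance synapses with delays.** Synaptic current is
  $I_{syn} = s\,G_e (E_e - v) + G_i (E_i - v)$ where $G_e, G_i$ are
  per-neuron conductance pools. All excitatory synapses onto a neuron share
  one decay constant $\tau_e$, so tracking the summed pool is exactly
  equivalent to tracking individual synaptic conductances; pools decay as
  $g\,e^{-dt/\tau}$ and spike deliveries add weight-sized increments after
  the synaptic delay (excitatory delays 11-16 ms, inhibitory 1-5 ms, drawn
  per synapse and rounded to the nearest step). The homeostatic scale $s$
  multiplies only the excitatory pool, and only at current-evaluation time.

* **Homeostatic scaling.** $s$ drifts up at $\omega_D/\tau_\omega$ per
  second and drops by $1/\tau_\omega$ at each spike
  ($\tau_\omega = 600$ s), so it is stationary exactly at the target rate
  $\omega_D$. The parameter table gives $\omega_D$ as a band,
  0.25-0.35 Hz; we read this as a per-neuron set point and draw each
  neuron's target uniformly from the band at build time. $s$ is clamped at
  0 from below, has no upper clamp, and starts at 1.

* **Plasticity.** Excitatory synapses use a nearest-neighbour triplet
  STDP rule: a pre-then-post pairing at lag $\Delta t \ge 0$ (ties
  included) adds $(\delta^{LTP}_e + \Delta w^{LTD}_e)\,
  e^{-\Delta t/\tau^{LTP}_e}$, where $\Delta w^{LTD}_e \le 0$ is that
  synapse's most recent depression, stored per synapse, overwritten at each
  depression and floored so a strong recent depression suppresses rather
  than inverts potentiation. A post-then-pre pairing adds
  $-\delta^{LTD}_e\, e^{-|\Delta t|/\tau^{LTD}_e}$. The depression branch
  is written with a decaying magnitude on its own time constant
  $\tau^{LTD}_e = 25$ ms (a formulation that reused the LTP constant
  with a growing exponent would leave $\tau^{LTD}_e$ unused and diverge
  for large lags, so the decaying form is the package's rule). Inhibitory synapses use a symmetric inverted
  top-hat window: near-coincident spikes ($|\Delta t| < 40$ ms) depress
  the weight by 0.05 nS (co-active neurons decouple their inhibition),
  lags in the 40-700 ms annulus potentiate it by 0.02 nS. An alternative
  branch order that tests the depression window first with its 700 ms
  constant would make the potentiation branch unreachable for the default
  constants, contradicting the rule's purpose of strengthening inhibition
  between independently firing neurons, so the default maps the inner
  window to the smaller constant; `literal_mode` preserves the
  alternative order for audit, and a regression test documents that its
  potentiation branch is dead code. Weights are clamped to
  $[0, 0.8]$ nS; the inhibitory lower table value 0.5 nS is used only to
  initialize (excitatory weights start uniform on $[0, 0.08)$ nS).

# Network variants

`build_simple()` (N = 480, all-to-all): each neuron pair carries both an
excitatory and an inhibitory synapse ("dual-role" neurons), so the net
effect of an ensemble on a neuron can swing from inhibitory to excitatory
as learning moves the two weights. Degrees are balanced exactly (at
$p < 1$ a configuration-model construction keeps in-degree = out-degree).
The weight matrices are stored 480 x 480 with a structurally zero
diagonal — a 230,400-entry weight space per synapse type.

`build_alternate()` (2000 excitatory + 500 fast-spiking inhibitory
neurons, Bernoulli 0.3 connectivity) separates the two pathways into
distinct populations, raises the excitatory capacitance to 500 pF and the
excitatory reversal to 30 mV (the parameter table's value; the running
text says 40 mV — we adopt the table and leave it config-overridable),
uses a 10x faster inhibitory conductance decay, a non-inverted top-hat on
i→i synapses, and one non-plastic feedback inhibitory neuron with the slow
decay constant wired to and from every excitatory neuron.

`build_preplay()` keeps the simple topology but slows the neurons
drastically: the four-parameter regular-spiking set with the
capacitance-like divisor at 1000, $a$ 1000x smaller and $d$ 10x smaller,
synaptic decays of 120/65 ms, excitatory reversal 30 mV, 10x larger
plasticity steps and the inverted inhibitory window (56 ms inner disc,
140 ms outer). These slow, stable dynamics let cue bursts ignite
self-sustained forward or reverse sequence recall.

Parameters the model family leaves open, fixed once here as package
defaults: the non-plastic input synapse is 4 nS in the simple variant
(rheobase is ~32 pA, so one 4 nS input spike at $s = 1$ is reliably
suprathreshold) and 16 nS in the preplay variant — with the default 4 nS
the high-capacitance preplay neuron stays essentially silent against
sustained pacing and recurrent inhibition; we swept {4, 8, 16, 30} nS once
and kept the smallest reliable value. The pacing inhibitory synapse is
0.1 nS (at 250 Hz against $\tau_i = 50$ ms this sustains ~1.25 nS of
rhythmic inhibition, enough to pace without silencing), and the feedback
neuron's synapses in the alternate variant are 0.5 nS.

# The stimulus

Episodes are ordered sequences of 30 temporal steps, each owned by a few
input neurons (4 in the default 480-input geometry). Twelve episodes are
allocated in blocks of four; in partitioned mode a block's episodes are
disjoint and tile the input population, in random mode members are drawn
without regard for reuse (the alternate variant's many-to-many wiring).
During a presentation, one low-frequency (theta-like, 7 Hz) cycle advances
the current step by one; within the cycle the current step fires in the
middle high-frequency (gamma-like, 49 Hz) block and the three trailing
steps in the blocks before it at decreasing intensity. The rendered
intensity model — up to 3 spikes per active block, each with probability
0.8 x intensity, intensities [1, 0.75, 0.5, 0.25], every spike jittered
within one gamma period — is calibrated so a participating neuron emits
$3 \times 0.8 \times 2.5 = 6$ spikes per presentation in expectation,
which is ~10.5 Hz over its four driven cycles. One member of every step is
dropped per presentation (recorded in the annotations; the basis of the
pattern-completion measure). Consecutive presentations overlap by four
temporal steps, so a new presentation starts every 26 cycles and the
trial-averaged episode drive per input neuron is
$6 \times 0.75 \times 0.25 / (26/7\,\mathrm{s}) \approx 0.30$ Hz —
matching the homeostatic set point by construction. Poisson noise spikes
($\nu = 0.05$ Hz per input neuron) and the 250 Hz pacing train with fixed
per-target 1-4 ms delays complete the drive. The somatic noise current is
zero-mean gaussian with $\sigma = 80$ pA, drawn independently per neuron
per 0.5 ms step and not rescaled with $dt$ (a per-step draw rather than
dt-scaled white noise; documented so the choice can be audited).

# Simulation engine

The engine advances in fixed steps with a strict within-step order:
conductance decay, due deliveries (ring buffer), external input enqueue,
noise draws, integration of all neurons, spike processing (reset,
homeostatic decrement, STDP against pre-step spike history with
simultaneous spikes pairing at zero lag, delivery enqueue with post-update
weights), homeostatic drift, recording. This order is part of the
contract because zero-lag STDP events depend on it. On each spike event
the triplet rule applies its potentiation branch on the afferent synapses
and its depression branch on the efferent ones (strictly post-then-pre,
so a zero-lag pair is potentiated exactly once); the symmetric top-hat
rule fires on both pre- and postsynaptic events against the other
endpoint's most recent spike. Presynaptic STDP traces use emission times;
conductances arrive after the synaptic delay. Runs abort with a
diagnostic naming the neuron and time on non-finite state or
$|v| > 10\,|v_p|$.

The compiled core (`run_network()`) and the scalar R reference
(`reference_run()`) implement this schedule independently and must
produce bit-identical spike streams under equal seeds; the test suite
asserts identity on ~10-neuron fixtures of all three variants. All
randomness flows through R's RNG, so a single seed reproduces a run
exactly; builders, allocators and renderers take their own seeds so each
component is separately reproducible.

# Analysis

The relative-activity metric
$R = (\mu_{group} - \mu_{background}) / (\mu_{active} - \mu_{background})$
uses 1/7 s bins (one per cycle). The prospection group contains recurrent
targets of the members of the next two temporal steps that are not
currently stimulated; the completion group the targets of the members
dropped from the current step; background are the input-silent non-member
recurrent neurons of the bin (the package's own definition of the
background group). Group means are averaged
over neurons, then over each presentation's bins, then over presentations;
an undefined denominator is flagged, never silently zeroed. Because these
groups receive no direct input while homeostasis regulates each neuron by
its total input, $R$ is expected to lie strictly inside $(0, 1)$ after
learning.

Replay/preplay events are scored by the Spearman rank correlation between
first-spike times in a window and template step indices (first-spike
latency, ties broken by neuron id), with a 1000-shuffle permutation gate
before any direction call and no call under five participants.
Weight-trajectory geometry embeds snapshot sequences with an established
neighborhood-preserving manifold method (isomap, via vegan) — the
embedding algorithm is deliberately delegated, not re-implemented — fits
one direction per learning group (first principal component of the
group's embedded points) and reports pairwise angles in degrees alongside
the same angles in raw weight space. Multi-seed summaries use medians; no
multiple-testing correction is applied (these are exploratory
diagnostics, not inference).

# Study conditions and problem sizes

The package's own validation runs use these scales, chosen once:

* **Stimulus calibration**: 220 presentations of the default 480-input,
  30-step geometry; the three drive statistics (6 spikes/presentation,
  ~10 Hz active, ~0.3 Hz trial-average) are recomputed from the rendered
  schedule.
* **Episode learning**: the simple variant at its native geometry
  (N = 480, one block of four 30-step episodes, default plasticity,
  homeostasis and noise) for 420 presentations (~1560 s simulated),
  three seeds, with $R$ evaluated over the final quarter of
  presentations. A more aggressive structural scale-down (N = 120 with
  6-step episodes) was rejected: shortening episodes while keeping the
  4-step presentation overlap compresses the schedule ~13-fold, driving
  input neurons at ~5 Hz instead of ~0.3 Hz, so homeostasis fights the
  stimulus instead of matching it and prospection never emerges. Keeping
  the native geometry and shortening the trial preserves the balance the
  model is built around.
* **Noise robustness**: three seeds at the highest noise of the sweep
  ($\nu = 0.5$ Hz, 10x the default) for 200 presentations; completion is
  compared against prospection.
* **Preplay/replay**: the preplay variant at N = 240 (2 members per
  step), 30 steps with 7-fold step repetition, 60 presentations, three
  seeds; recall is cued 1 s into an 8 s noise-driven run and scored over
  the remainder.
* **Homeostatic regulation**: a 30-neuron network driven only by noise
  for 5000 s; the median rate of the second half is checked against the
  $[\omega_D/2,\ 2\omega_D]$ bracket. Convergence is slow (the drift
  rate is $\omega_D/\tau_\omega \approx 5 \times 10^{-4}$/s), which is
  why this check needs the longest simulated time despite the smallest
  network.

# What the generator does and does not emulate

The synthetic stimulus reproduces the structure the model was designed
for: nested theta/gamma drive, per-presentation dropout, Poisson input
noise, somatic current noise and uniform episode selection. It does not
emulate place-field geometry, real sensory statistics, correlated noise,
or trial-to-trial nonstationarity in drive intensity; passing tests
therefore show that the mechanisms (homeostasis, the two STDP rules, the
pacing rhythm) interact as described under the stated drive statistics,
not that the model would learn from arbitrary in-vivo spike trains.

# Numerical choices and degenerate inputs

Delays are rounded to the nearest step with `floor(x/dt + 0.5)` (no
banker's rounding, identical in both engines) and are at least one step,
so no delivery is instantaneous. Spike times are stamped at end-of-step.
Weight clamps are applied after every individual update. Degenerate
analysis inputs are flagged rather than absorbed: an order score with
fewer than five participants makes no direction call, a zero-length
trajectory segment yields NA angles with a warning, and an R metric with
a non-positive denominator is marked undefined. Episode allocation
rejects populations that do not divide evenly into steps, and the
many-to-many projection rejects infeasible degree constraints.

# Known limitations

Learning at the model's full scale (three blocks of four episodes in
sequence, hours of simulated time) is supported by the code but not
exercised by the default validation runs, which train a single block.
The alternate variant is validated structurally and for engine
equivalence, not for full-scale learning. Prospection under the default
conditions is reliably positive but small (R of order 0.03 after ~1500 s;
completion reaches ~0.15-0.2), and continues to grow with training time;
the package asserts the direction and bounds of these effects rather
than any particular magnitude. The preplay variant's recall speed is far
slower than biological replay timescales, a known property of the
high-capacitance design.
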