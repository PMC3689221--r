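# episodenet

Recurrent spiking neural networks that learn noisy spike-pattern episodes
— and prospectively recall them.

Sequences of neural activity in recurrent circuits such as hippocampal CA3
are learned from presentations that are noisy, incomplete and variable in
intensity. `episodenet` implements a family of recurrent
spiking-neural-network models in which three mechanisms cooperate to make
that learning stable:

* **conductance-based Izhikevich neurons** with delayed excitatory and
  inhibitory synapses,
* **two complementary STDP rules** — a nearest-neighbour *triplet* rule on
  excitatory synapses,
  Δw = (δ<sup>LTP</sup><sub>e</sub> + Δw<sup>LTD</sup><sub>e</sub>)·e<sup>−Δt/τLTP</sup>
  for pre-then-post pairings and −δ<sup>LTD</sup><sub>e</sub>·e<sup>−|Δt|/τLTD</sup>
  for post-then-pre, and a symmetric *inverted top-hat* rule on inhibitory
  synapses that decouples co-active neurons (|Δt| < 40 ms depresses, lags
  up to 700 ms potentiate), and
* **homeostatic scaling** of each neuron's total excitatory input,
  s′ = ω<sub>D</sub>/τ<sub>ω</sub> with s ← s − 1/τ<sub>ω</sub> per spike,
  which anchors every neuron to a target rate ω<sub>D</sub> ≈ 0.3 Hz.

Episodes are 30-step spatiotemporal patterns delivered as nested
theta/gamma drive (7 Hz cycles, 49 Hz blocks, trailing steps at decreasing
intensity), with one member of each step dropped per presentation and
Poisson background noise. After training, the network fires *prospectively*
(members of upcoming, not-yet-stimulated steps) and *completes* the dropped
members; both are quantified by the relative-activity metric

> R = (μ<sub>group</sub> − μ<sub>background</sub>) / (μ<sub>active</sub> − μ<sub>background</sub>)

which lies strictly between 0 and 1 when homeostasis is doing its job. A
slowed, high-capacitance *preplay* variant goes further: after learning, a
brief cue from an episode's first two steps ignites forward preplay of the
whole sequence, and a cue from the last two steps ignites reverse replay.

The package provides the three network builders (`build_simple`,
`build_alternate`, `build_preplay`), the stimulus generator
(`allocate_episodes`, `make_stimulus`, `cue_pattern`, …), a fast compiled
simulation engine (`run_network`) with a scalar R reference implementation
(`reference_run`) that must agree spike-for-spike, and the analysis layer
(`compute_R`, `learning_curve`, `rate_map`, `replay_order_score`,
`weight_segment_angles`). A thin CLI lives at `inst/cli/episodenet.R`.
See the vignette `episode-learning-methods` for the full model account.

## Worked example

Calibrate the stimulus, train the simple variant on one block of four
episodes, and measure prospection and completion:

```r
library(episodenet)

st <- stimulus_statistics(n_presentations = 220, seed = 42)
#> spikes/presentation: 6.001
#> active-cycle rate:   10.50 Hz
#> trial-average rate:  0.3026 Hz
```

A participating input neuron emits ~6 spikes per presentation of its
episode — a brief ~10 Hz burst rate while its step is active that averages
out to ~0.3 Hz over the trial, i.e. exactly the homeostatic set point.

```r
run <- train_episode_network("simple", N = 480, n_steps = 30,
                             n_presentations = 420, seed = 1)
ev <- evaluate_R(run)   # final quarter of the presentations
ev$R_prospection
#> <rmetric_result> prospection : R = 0.0269
#>   mu_group = 0.627  mu_active = 23.251  mu_background = 0.002 Hz (105 presentations)
ev$R_completion
#> <rmetric_result> completion : R = 0.1763
#>   mu_group = 4.100  mu_active = 23.251  mu_background = 0.002 Hz (105 presentations)
```

After ~1560 s of simulated learning, neurons whose input was dropped fire
at ~18% of the directly driven level and upcoming-step neurons fire above
background (both R in (0, 1), as the homeostatic argument predicts), while
background activity is almost completely suppressed. The learning curve
(`learning_curve(run$result, run$stim, run$graph)`) rises monotonically in
presentation index, and with the preplay variant
(`train_episode_network("preplay", ...)` + `cue_recall`) start-cues yield
positive and end-cues negative rank-order scores.

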