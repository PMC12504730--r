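---
title: "Channel-specific cholinergic gating of striatal reinforcement learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel-specific cholinergic gating of striatal reinforcement learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(striatumgate)
```

## The model

The simulator implements a channelized striatal circuit learning
stimulus–action associations by trial and error. Each *channel* — the unit
of action representation — contains a population of D1 (direct-pathway)
and D2 (indirect-pathway) projection neurons and a single action neuron.
All neurons are leaky integrate-and-fire units with current-based delta
synapses,

$$\tau_m \frac{dV}{dt} = -V + \tau_m \sum_k w_k \sum_{t_k} \delta(t - t_k) + I_{bg} + \xi(t),$$

with dimensionless voltage (rest = reset = 0, threshold 1), a refractory
period of 2 ms, and a 1 ms clock step. D2 SPNs are more excitable than D1
(threshold reduced by 10 %), supporting their role in suppression.

Cortical input neurons project to every SPN through two plastic weight
matrices (one per SPN type), bounded in $[0, w_{max}]$. D1 SPNs excite and
D2 SPNs inhibit their channel's action neuron; action neurons inhibit each
other (a winner-take-all selection race); and SPN collaterals provide
asymmetric lateral inhibition, D2→D1 stronger than D1→D2, within the
channel (a configurable fraction, default 0, acts across channels).

An action-neuron spike does two things: it registers the behavioural
response, and it opens (or refresh-extends) a **150 ms cholinergic window
in its own channel**. The window is the model's abstraction of the pause
in tonically active cholinergic interneurons that follows action
initiation; the interneurons themselves and their thalamic drivers are not
modelled.

### Three-factor plasticity

Eligibility accumulates as exponentially decaying pre/post trace
coincidences ($\tau_+ = \tau_- = 20$ ms), **only while the postsynaptic
channel's ACh gate is open**. Pre-before-post and post-before-pre pairings
are accumulated separately; a simultaneous pair counts as pre-before-post.
A global dopamine pulse — reward after a correct response, punishment
after an incorrect one, nothing after no response — converts eligibility
into weight change at trial end:

$$\Delta w = \eta\,(A^+_{type,val}\,E_{prepost} + A^-_{type,val}\,E_{postpre}).$$

The kernel sign table follows pathway physiology: D1 potentiates under
reward $(+1, -0.5)$ and depresses under punishment $(-0.5, 0)$; D2
depresses under reward $(-0.3, 0)$ and potentiates under punishment
$(+0.7, -0.5)$, so punished channels recruit indirect-pathway suppression.
Three further stabilisers shape the update:

* a per-pulse step cap (`dw_cap`, default 0.1; punishment cap 0.2), so a
  single trial cannot move a synapse arbitrarily far when firing rates —
  and hence eligibility — are large. Punishment steps are larger than
  reward steps so that pruning of wrong associations outpaces their
  incidental reinforcement on rewarded trials;
* soft-bounded potentiation (scaled by $1 - w/w_{max}$), the standard
  weight-dependent LTP form;
* once per trial, multiplicative postsynaptic LTD,
  $w \leftarrow w\,(1 - \lambda\, n_{post})$ with $\lambda = 10^{-4}$ per
  spike, which bounds weights near the fixed point
  $w^* \approx P/(\lambda r)$ for potentiation inflow $P$ and activity
  $r$, and erases stale associations after contingency changes.

Three rule variants support the gating comparison: `classic` (spike timing
only, applied every trial), `reward_modulated` (dopamine-dependent but
ungated — global modulation), and `da_ach_gated` (the full rule). We gate
the *accumulation* of eligibility rather than only its conversion; with
eligibility persisting to trial end the two readings differ only for
coincidences outside any gate, which the gated reading discards.

## The behavioural tasks

Each 2 s trial presents one relevant stimulus (plus all configured
distractors) as a spatiotemporal spike pattern: the stimulus's input
population (20 neurons by default) is split into 5 sequential blocks that
tile the trial, each firing Poisson spikes at 40 Hz while active. The
first 200 ms of the trial are an exclusion period — responses there are
premature and ignored. The first post-exclusion action spike per channel
is that channel's single action event. A trial is rewarded only if all
counted actions are the correct channel; any incorrect action punishes the
trial, even when a correct action also occurred; no counted action yields
no dopamine at all (counted as incorrect for accuracy, but inaction is not
punished). Contingency reversals permute the mapping (a swap for two
relevant stimuli, a cyclic shift for more) at configured episodes.

Exploration is driven by Poisson input stochasticity plus Gaussian
membrane noise and a constant subthreshold background drive on the action
neurons, so a channel with no learned input still acts occasionally. This
is the model's only source of behavioural variability; there is no
explicit epsilon-greedy policy in the spiking agent.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `tau_m` / `tau_m_act` | 10 / 100 ms | SPN / action-neuron membrane time constants; the slow action integrator averages pathway evidence rather than instantaneous spike noise |
| `d2_excitability` | 0.10 | D2 threshold reduction |
| `w_d1_act`, `w_d2_act` | 0.02, −0.03 | static SPN→action weights |
| `w_act_act` | −2 | winner-take-all inhibition between action neurons |
| `w_d2_d1`, `w_d1_d2` | −0.25, −0.02 | within-channel lateral inhibition; the strong D2→D1 branch cancels common-mode excitation at the D1 stage |
| `lat_cross_frac` | 0 | fraction of lateral inhibition acting across channels |
| `sigma_spn`, `sigma_act` | 0.16, 0.021 | per-step membrane noise; `sigma_spn` keeps SPNs sparsely active at zero weight so silent channels can re-learn |
| `bg_act` | 0.007 | background drive to action neurons (exploration floor) |
| `w_max`, `w_init` | 4, 0.5 | weight bound and constant initial value |
| `ach_window` | 150 ms | cholinergic gate duration |
| `da_delay`, `da_duration` | 200, 50 ms | dopamine pulse timing (bookkeeping; learning applies at trial end) |
| `learning_rate` | 0.05 | dopamine conversion step |
| `lambda_ltd` | 1e-4 /spike | multiplicative LTD coefficient |

All quantitative values are package defaults chosen so that the mechanism
expresses its qualitative behaviour — fast specific baseline learning,
gating-dependent channel specificity, reversal adaptation with transient
D2 recruitment — at desk-scale problem sizes; every one is exposed in
`network_config()` / `plasticity_config()` and the YAML experiment config.

## What the synthetic tasks do and do not emulate

The generator reproduces the *structure* of the behavioural battery:
sequential stimulus activation, simultaneous distractors, delayed binary
outcomes, contingency reversals. It does not emulate realistic cortical
sequence statistics, probabilistic or graded rewards, inter-trial
dependence, or reward-prediction-error dopamine (pulses here have fixed
amplitude regardless of expectation). Passing tests therefore demonstrate
properties of the learning mechanism under controlled Poisson input, not
performance on biological recordings.

## Numerical and design choices

* Clock-driven simulation at dt = 1 ms in compiled code; traces decay by
  `exp(-dt/tau)` per step, making binned eligibility exact for
  grid-aligned spikes. An event-driven R implementation of the same
  arithmetic serves as an independent oracle in the tests (agreement to
  1e-9 against brute-force pairwise sums).
* Membrane state, traces, gates and eligibility reset at trial
  boundaries; only weights persist. Eligibility persists within the trial
  until the (delayed) dopamine pulse and is consumed by it.
* The dopamine pulse selects the kernel by valence tag; punishment is an
  outcome-specific kernel, not a negative-amplitude reward pulse.
* Between-channel RNG: the schedule, per-trial stimulus spikes and network
  noise draw from independently derived seed streams, so the environment
  is reproducible independent of network noise.
* Block means over (stimulus population × channel population) are the
  summary statistic for weight matrices, matching how the learned
  structure is analysed and stored in snapshots (every 10 episodes by
  default).
* Accuracy for log-log fits uses the seed-averaged smoothed curve as a
  fraction; the low-accuracy regime is < 0.79. Remap time after a reversal
  is measured to the first recovery of the smoothed reward rate to its
  pre-reversal 100-episode mean minus five percentage points, after
  having dipped below it.
* Paired comparisons report d_z = t/sqrt(n). Identical samples return
  t = 0, d = 0; zero-variance differences with nonzero mean are an error.

## Known limitations

* With eight simultaneous distractors the reward rate at episode 1000
  averages ~53 % (chance 50 %) across seeds and keeps fluctuating:
  reward potentiates every gated active synapse, so distractor weights
  cannot be pruned below the level at which their common-mode drive
  competes with the relevant-stimulus margin. Hand-constructed weight
  states with pruned distractors achieve ~100 % frozen accuracy, so the
  limitation lies in the learning dynamics as specified, not the
  architecture.
* The tabular Q-learning baseline (contextual bandit, rewards ±1, zero
  init) is invariant to the learning rate — only epsilon and the action
  count shape its curve — and its accuracy starts at the 1/N floor, so
  early power-law slopes are shallow for small N and steepen with task
  size (0.77 at N = 32).
* Multiplicative LTD erases outdated associations rather than suppressing
  them; there is no spontaneous recovery or savings after reversal.
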