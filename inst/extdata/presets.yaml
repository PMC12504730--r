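# Experiment presets: one section per study setting.
# Task fields omitted here fall back to task_config() defaults.
baseline:
  agent: snn
  mode: da_ach_gated
  n_seeds: 1
  n_channels: 2
  n_relevant: 2
  n_distractors: 0
  n_episodes: 10000
credit_assignment:
  agent: snn
  mode: da_ach_gated
  n_seeds: 100
  n_channels: 2
  n_relevant: 2
  n_distractors: 8
  n_episodes: 10000
  grid:
    n_distractors: [0, 1, 2, 3, 4, 5, 6, 7, 8]
reversal_single:
  agent: snn
  mode: da_ach_gated
  n_seeds: 50
  n_channels: 2
  n_relevant: 2
  n_distractors: 8
  n_episodes: 2000
  reversal_episodes: [500]
reversal_repeated:
  agent: snn
  mode: da_ach_gated
  n_seeds: 1
  n_channels: 2
  n_relevant: 2
  n_distractors: 8
  n_episodes: 10000
  reversal_episodes: [2000, 4000, 6000, 8000]
scaling:
  agent: both
  mode: da_ach_gated
  n_seeds: 20
  n_channels: 4
  n_relevant: 4
  n_distractors: 0
  n_episodes: 10000
  grid:
    n_actions: [4, 8, 16, 32]
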