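Package: striatumgate
Title: Spiking Striatal Action Selection with Acetylcholine-Gated
    Three-Factor Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clock-driven simulation of a channelized striatal circuit in
    which direct-pathway (D1) and indirect-pathway (D2) projection neurons
    learn stimulus-action associations through a three-factor
    spike-timing-dependent plasticity rule: eligibility traces are gated by
    brief channel-specific acetylcholine windows opened by action execution
    and converted into weight changes by global dopamine reward and
    punishment signals, with a multiplicative postsynaptic long-term
    depression term bounding the weights. Provides the behavioural task
    battery (distractor stimuli, contingency reversals, scaling action
    spaces), a tabular Q-learning baseline on the identical tasks, and the
    statistical analyses: Gaussian-smoothed learning curves, power-law fits
    of the low-accuracy regime, paired t-tests with Cohen's d, remap times
    and D2/D1 activity ratios.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
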