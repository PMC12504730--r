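# Shared fixtures and independent oracles.

tiny_task <- function(...) {
  task_config(n_channels = 2L, n_relevant = 2L, n_distractors = 0L,
              n_episodes = 10L, pop_size = 20L, ...)
}

# Brute-force pairwise STDP sums: for every (pre spike, post spike) pair,
# pre-before-post pairs (t_post >= t_pre) contribute exp(-(dt)/tau_plus) to
# the prepost sum, post-before-pre pairs (t_pre > t_post) contribute
# exp(-(dt)/tau_minus) to the postpre sum; a pair counts only when its later
# spike falls inside an open gate of the postsynaptic channel. Independent
# of the trace-based implementation.
brute_force_eligibility <- function(pre, post, post_channel, gates,
                                    tau_plus = 20, tau_minus = 20) {
  n_in <- length(pre); n_post <- length(post)
  in_gate <- function(ch, t) {
    if (is.null(gates)) return(TRUE)
    if (!nrow(gates)) return(FALSE)
    any(gates$channel == ch & t > gates$open & t <= gates$close)
  }
  E_pp <- matrix(0, n_in, n_post); E_qp <- matrix(0, n_in, n_post)
  for (i in seq_len(n_in)) for (j in seq_len(n_post)) {
    for (tp in pre[[i]]) for (tq in post[[j]]) {
      if (tq >= tp) {
        if (in_gate(post_channel[[j]], tq))
          E_pp[i, j] <- E_pp[i, j] + exp(-(tq - tp) / tau_plus)
      } else {
        if (in_gate(post_channel[[j]], tp))
          E_qp[i, j] <- E_qp[i, j] + exp(-(tp - tq) / tau_minus)
      }
    }
  }
  list(prepost = E_pp, postpre = E_qp)
}

random_spike_train <- function(n, t_max = 500) sort(runif(n, 0, t_max))
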