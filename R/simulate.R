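# Seed derivation and substream helpers. Component streams (trial schedule,
# per-trial stimulus spikes, network noise) are independently reproducible:
# the schedule and one spike seed per episode are drawn up front from an
# env stream; during the run the network-noise stream is saved and restored
# around each trial's spike generation.

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 59999L) * 31013 + 7919 * k) %% 2147483629L + 1L
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

# 1-based row indices of input neurons belonging to each stimulus, and
# column indices of SPNs belonging to each channel.
stimulus_partition <- function(task) {
  lapply(seq_len(n_stimuli(task)) - 1L,
         function(s) s * task$pop_size + seq_len(task$pop_size))
}

channel_partition <- function(n_channels, n_per_channel) {
  lapply(seq_len(n_channels) - 1L,
         function(c) c * n_per_channel + seq_len(n_per_channel))
}

#' Run a full spiking-network experiment for one seed
#'
#' Simulates \code{task$n_episodes} trials end-to-end: schedule generation,
#' stimulus spike generation, circuit simulation, adjudication, dopamine
#' delivery and plasticity, applying contingency reversals at the configured
#' episodes. Reproducible: identical configs and seed give identical output.
#'
#' @param task a \code{\link{task_config}}.
#' @param network a \code{\link{network_config}} (its \code{n_channels}
#'   must match the task's).
#' @param plasticity a \code{\link{plasticity_config}}.
#' @param seed integer run seed.
#' @param snapshot_every record block-mean weight summaries every this many
#'   episodes (also always at the last episode); 0 disables.
#' @return list with \code{outcomes} (one row per episode: \code{episode},
#'   \code{relevant_stimulus}, \code{action}, \code{latency_ms},
#'   \code{rewarded}, \code{punished}, \code{premature_only}, \code{epoch},
#'   \code{d1_spikes}, \code{d2_spikes}), \code{snapshots} (long data.frame
#'   of block-mean weights per episode x stimulus x channel), \code{W1},
#'   \code{W2} (final matrices), \code{map} (final mapping), \code{task},
#'   \code{network}, \code{plasticity}, \code{seed}.
#' @export
run_snn_experiment <- function(task, network = network_config(task$n_channels),
                               plasticity = plasticity_config(),
                               seed = task$seed, snapshot_every = 10L) {
  validate_task_config(task)
  if (network$n_channels != task$n_channels)
    stop("network and task disagree on n_channels")
  patterns <- make_stimulus_patterns(task)
  n_in <- n_stimuli(task) * task$pop_size
  state <- build_network(network, n_in)
  map <- stimulus_action_map(task)
  sched <- with_seed(derive_seed(seed, 1L), {
    s <- schedule_trials(task)
    attr(s, "trial_seeds") <- sample.int(2147483646L, task$n_episodes,
                                         replace = TRUE)
    s
  })
  distractors <- attr(sched, "distractors")
  trial_seeds <- attr(sched, "trial_seeds")
  sp_stim <- stimulus_partition(task)
  cp_d1 <- channel_partition(network$n_channels, network$n_d1)
  cp_d2 <- channel_partition(network$n_channels, network$n_d2)

  n_ep <- task$n_episodes
  rewarded <- logical(n_ep); punished <- logical(n_ep)
  premature <- logical(n_ep); action <- rep(NA_integer_, n_ep)
  latency <- rep(NA_real_, n_ep); epoch <- integer(n_ep)
  d1_spikes <- integer(n_ep); d2_spikes <- integer(n_ep)
  snaps <- list()

  set.seed(derive_seed(seed, 2L))  # network-noise stream
  for (e in seq_len(n_ep)) {
    map <- apply_reversal(map, e, task)
    rel <- sched$relevant_stimulus[[e]]
    active <- patterns[c(rel, distractors) + 1L]
    spikes <- with_seed(trial_seeds[[e]], generate_trial_spikes(active))
    tr <- run_trial(state, spikes, map, rel, task, plasticity,
                    episode = e, distractors = distractors)
    state <- tr$state
    rewarded[[e]] <- tr$outcome$rewarded
    punished[[e]] <- tr$outcome$punished
    premature[[e]] <- tr$outcome$premature_only
    action[[e]] <- tr$outcome$action
    latency[[e]] <- tr$outcome$latency_ms
    epoch[[e]] <- map$epoch
    d1_spikes[[e]] <- sum(tr$d1_count)
    d2_spikes[[e]] <- sum(tr$d2_count)
    if (snapshot_every > 0L &&
        (e %% snapshot_every == 0L || e == n_ep)) {
      ws <- weight_summary(state$W1, state$W2, sp_stim,
                           list(D1 = cp_d1, D2 = cp_d2))
      snaps[[length(snaps) + 1L]] <- data.frame(
        episode = e,
        stimulus = rep(seq_len(n_stimuli(task)) - 1L,
                       times = network$n_channels),
        channel = rep(seq_len(network$n_channels) - 1L,
                      each = n_stimuli(task)),
        d1 = as.vector(ws$d1), d2 = as.vector(ws$d2),
        diff = as.vector(ws$diff))
    }
  }
  list(outcomes = data.frame(
         episode = seq_len(n_ep),
         relevant_stimulus = sched$relevant_stimulus,
         action = action, latency_ms = latency,
         rewarded = rewarded, punished = punished,
         premature_only = premature, epoch = epoch,
         d1_spikes = d1_spikes, d2_spikes = d2_spikes),
       snapshots = if (length(snaps)) do.call(rbind, snaps) else NULL,
       W1 = state$W1, W2 = state$W2, map = map,
       task = task, network = network, plasticity = plasticity,
       seed = seed)
}
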