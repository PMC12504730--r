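#' Task configuration
#'
#' Defines one behavioural task: how many action channels and stimuli exist,
#' how stimuli are rendered as spatiotemporal spike patterns, and when
#' stimulus-action contingencies reverse. Each trial spans
#' \code{trial_duration} ms, of which the first \code{exclusion_period} ms
#' are an exclusion period during which responses are premature and ignored.
#'
#' @param n_channels number of action channels.
#' @param n_relevant number of relevant (reward-predictive) stimuli; must not
#'   exceed \code{n_channels}.
#' @param n_distractors number of distractor stimuli (0--8), co-presented on
#'   every trial but never reward-predictive.
#' @param trial_duration trial length in ms.
#' @param exclusion_period initial exclusion period in ms.
#' @param n_episodes number of trials (episodes) in a run.
#' @param reversal_episodes integer vector of episode indices (1-based,
#'   strictly increasing, < \code{n_episodes}) at which the stimulus-action
#'   mapping is permuted; the new mapping is in effect from that episode on.
#' @param pop_size input neurons per stimulus.
#' @param rate_active firing rate (Hz) of a stimulus block while active.
#' @param n_blocks number of sequential sub-population blocks a stimulus
#'   pattern is divided into; blocks tile the trial duration.
#' @param seed integer seed controlling schedule and spike generation.
#' @return an object of class \code{task_config}.
#' @export
task_config <- function(n_channels = 2L, n_relevant = 2L, n_distractors = 0L,
                        trial_duration = 2000, exclusion_period = 200,
                        n_episodes = 1000L, reversal_episodes = integer(0),
                        pop_size = 20L, rate_active = 40, n_blocks = 5L,
                        seed = 1L) {
  cfg <- list(n_channels = as.integer(n_channels),
              n_relevant = as.integer(n_relevant),
              n_distractors = as.integer(n_distractors),
              trial_duration = trial_duration,
              exclusion_period = exclusion_period,
              n_episodes = as.integer(n_episodes),
              reversal_episodes = as.integer(reversal_episodes),
              pop_size = as.integer(pop_size),
              rate_active = rate_active,
              n_blocks = as.integer(n_blocks),
              seed = as.integer(seed))
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (cfg$n_channels < 1L) stop("n_channels must be >= 1")
  if (cfg$n_relevant < 1L) stop("n_relevant must be >= 1")
  if (cfg$n_relevant > cfg$n_channels)
    stop("n_relevant must not exceed n_channels")
  if (cfg$n_distractors < 0L || cfg$n_distractors > 8L)
    stop("n_distractors must be between 0 and 8")
  if (cfg$pop_size < 1L) stop("pop_size must be >= 1")
  if (cfg$n_blocks < 1L) stop("n_blocks must be >= 1")
  if (!(cfg$trial_duration > cfg$exclusion_period &&
        cfg$exclusion_period > 0))
    stop("need trial_duration > exclusion_period > 0")
  if (cfg$n_episodes < 1L) stop("n_episodes must be >= 1")
  if (length(cfg$reversal_episodes)) {
    re <- cfg$reversal_episodes
    if (any(diff(re) <= 0) || any(re < 1L) || any(re >= cfg$n_episodes))
      stop("reversal_episodes must be strictly increasing and < n_episodes")
  }
  invisible(cfg)
}

n_stimuli <- function(cfg) cfg$n_relevant + cfg$n_distractors

#' Build spatiotemporal stimulus templates
#'
#' Each stimulus owns a disjoint block of input-neuron indices of size
#' \code{pop_size}. The block is split into \code{n_blocks} sequential
#' sub-populations that tile the trial duration, so that within a trial the
#' stimulus activates its neurons in a fixed temporal order (a synthetic
#' stand-in for sequential cortical/hippocampal activity).
#'
#' Relevant stimuli get ids \code{0..n_relevant-1}; distractors follow.
#'
#' @param config a \code{task_config}.
#' @return list of stimulus patterns; each has \code{stimulus_id},
#'   \code{neurons} (0-based index range, as \code{c(lo, hi)} half-open) and
#'   a \code{segments} data.frame with columns \code{neuron_lo},
#'   \code{neuron_hi} (half-open), \code{onset}, \code{offset}, \code{rate}.
#' @export
make_stimulus_patterns <- function(config) {
  validate_task_config(config)
  ns <- n_stimuli(config)
  if (ns < 1L) stop("no stimuli configured")
  pop <- config$pop_size
  nb <- min(config$n_blocks, pop)
  edges_n <- round(seq(0, pop, length.out = nb + 1L))
  edges_t <- seq(0, config$trial_duration, length.out = nb + 1L)
  lapply(seq_len(ns) - 1L, function(s) {
    base <- s * pop
    seg <- data.frame(
      neuron_lo = base + edges_n[-(nb + 1L)],
      neuron_hi = base + edges_n[-1L],
      onset     = edges_t[-(nb + 1L)],
      offset    = edges_t[-1L],
      rate      = config$rate_active)
    seg <- seg[seg$neuron_hi > seg$neuron_lo, , drop = FALSE]
    list(stimulus_id = s, neurons = c(base, base + pop), segments = seg)
  })
}

#' Generate Poisson input spikes for one trial
#'
#' Draws an independent homogeneous Poisson spike train for every neuron of
#' every active stimulus, at its segment rate within the segment window.
#' Inactive stimuli contribute nothing (background rate is zero).
#'
#' @param patterns list of stimulus patterns (the active set for this trial).
#' @return data.frame with columns \code{time_ms}, \code{neuron_id}
#'   (0-based), sorted by time.
#' @export
generate_trial_spikes <- function(patterns) {
  if (!length(patterns))
    return(data.frame(time_ms = numeric(0), neuron_id = integer(0)))
  tt <- list(); ii <- list(); k <- 0L
  for (p in patterns) {
    for (r in seq_len(nrow(p$segments))) {
      seg <- p$segments[r, ]
      dur_s <- (seg$offset - seg$onset) / 1000
      if (seg$rate <= 0 || dur_s <= 0) next
      for (nid in seq.int(seg$neuron_lo, seg$neuron_hi - 1L)) {
        n <- stats::rpois(1L, seg$rate * dur_s)
        if (n > 0L) {
          k <- k + 1L
          tt[[k]] <- seg$onset + stats::runif(n, 0, seg$offset - seg$onset)
          ii[[k]] <- rep.int(nid, n)
        }
      }
    }
  }
  if (k == 0L)
    return(data.frame(time_ms = numeric(0), neuron_id = integer(0)))
  out <- data.frame(time_ms = unlist(tt), neuron_id = unlist(ii))
  out[order(out$time_ms), , drop = FALSE]
}

#' Schedule the trial sequence
#'
#' Each episode draws one relevant stimulus uniformly at random; all
#' configured distractors are co-presented on every trial.
#'
#' @param config a \code{task_config}. Uses the current RNG state; seed
#'   management is up to the caller (see \code{\link{run_snn_experiment}}).
#' @return data.frame with columns \code{episode}, \code{relevant_stimulus};
#'   the distractor id set (identical every trial) is attached as attribute
#'   \code{"distractors"}.
#' @export
schedule_trials <- function(config) {
  validate_task_config(config)
  rel <- sample.int(config$n_relevant, config$n_episodes, replace = TRUE) - 1L
  out <- data.frame(episode = seq_len(config$n_episodes),
                    relevant_stimulus = rel)
  attr(out, "distractors") <-
    if (config$n_distractors > 0L)
      seq.int(config$n_relevant, length.out = config$n_distractors) else integer(0)
  out
}

#' Initial stimulus-action mapping
#'
#' Relevant stimulus \code{i} maps to channel \code{i}. Distractors carry no
#' mapping.
#' @param config a \code{task_config}.
#' @return a \code{stimulus_action_map}: list with \code{mapping} (named
#'   integer vector, stimulus id -> channel id) and \code{epoch} (0 before
#'   any reversal).
#' @export
stimulus_action_map <- function(config) {
  m <- seq_len(config$n_relevant) - 1L
  names(m) <- as.character(m)
  structure(list(mapping = m, epoch = 0L), class = "stimulus_action_map")
}

#' Apply a contingency reversal
#'
#' At each configured reversal episode the mapping over relevant stimuli is
#' permuted by a derangement: a swap for two relevant stimuli, a cyclic shift
#' for more. At all other episodes the map is returned unchanged. The new
#' mapping is in effect from the reversal episode onward.
#'
#' @param map a \code{stimulus_action_map}.
#' @param episode current episode index (1-based).
#' @param config a \code{task_config}.
#' @return the (possibly permuted) map; \code{epoch} increments on reversal.
#' @export
apply_reversal <- function(map, episode, config) {
  if (!episode %in% config$reversal_episodes) return(map)
  n <- length(map$mapping)
  if (n < 2L) stop("reversal undefined for a single relevant stimulus")
  map$mapping <- map$mapping[c(seq_len(n)[-1L], 1L)]  # cyclic shift of values
  names(map$mapping) <- as.character(seq_len(n) - 1L)
  map$epoch <- map$epoch + 1L
  map
}

#' Adjudicate a trial's actions into an outcome
#'
#' Actions before the exclusion period are discarded as premature. If at
#' least one counted action occurred and all counted actions are in the
#' correct channel the trial is rewarded; if any counted action is in an
#' incorrect channel it is punished (even when a correct action also
#' occurred); with no counted action the trial is neither rewarded nor
#' punished and is flagged.
#'
#' @param actions data.frame with columns \code{channel}, \code{time_ms},
#'   sorted by time (one collapsed event per channel).
#' @param map a \code{stimulus_action_map}.
#' @param relevant_stimulus id of this trial's relevant stimulus.
#' @param config a \code{task_config}.
#' @param episode episode index recorded in the outcome.
#' @param distractors distractor id set recorded in the outcome.
#' @return a \code{trial_outcome} list: \code{episode},
#'   \code{relevant_stimulus}, \code{distractors}, \code{actions}
#'   (counted actions), \code{action} (first counted channel or \code{NA}),
#'   \code{latency_ms}, \code{rewarded}, \code{punished},
#'   \code{premature_only}.
#' @export
evaluate_response <- function(actions, map, relevant_stimulus, config,
                              episode = NA_integer_, distractors = integer(0)) {
  if (nrow(actions) &&
      (any(actions$channel < 0L) || any(actions$channel >= config$n_channels)))
    stop("unknown channel id in actions")
  premature <- nrow(actions) > 0L &&
    all(actions$time_ms < config$exclusion_period)
  counted <- actions[actions$time_ms >= config$exclusion_period, , drop = FALSE]
  correct <- unname(map$mapping[as.character(relevant_stimulus)])
  if (is.na(correct)) stop("relevant stimulus has no mapped action")
  rewarded <- FALSE; punished <- FALSE
  if (nrow(counted)) {
    if (any(counted$channel != correct)) punished <- TRUE
    else rewarded <- TRUE
  }
  structure(list(
    episode = episode,
    relevant_stimulus = relevant_stimulus,
    distractors = distractors,
    actions = counted,
    action = if (nrow(counted)) counted$channel[[1L]] else NA_integer_,
    latency_ms = if (nrow(counted)) counted$time_ms[[1L]] else NA_real_,
    rewarded = rewarded, punished = punished,
    premature_only = premature), class = "trial_outcome")
}
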