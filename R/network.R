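#' Network configuration
#'
#' Parameters of the channelized striatal circuit. All neurons are leaky
#' integrate-and-fire with dimensionless membrane potential (rest = reset =
#' 0, threshold 1) and current-based delta synapses. D2 SPNs are more
#' excitable than D1: their threshold is reduced by \code{d2_excitability}.
#' Each channel holds \code{n_d1} D1 SPNs, \code{n_d2} D2 SPNs and one
#' action neuron; D1 excites and D2 inhibits the channel's action neuron,
#' and lateral inhibition is asymmetric (|D2 -> D1| > |D1 -> D2|), within
#' and across channels.
#'
#' @param n_channels number of action channels.
#' @param n_d1,n_d2 SPNs of each type per channel.
#' @param tau_m SPN membrane time constant (ms).
#' @param tau_m_act action-neuron membrane time constant (ms); slower than
#'   the SPNs' so that action selection integrates sustained pathway drive
#'   rather than instantaneous spike noise.
#' @param v_th,v_reset threshold and reset potential (dimensionless).
#' @param refractory refractory period (ms).
#' @param d2_excitability fractional threshold reduction for D2 SPNs.
#' @param w_d1_act,w_d2_act static SPN-to-action-neuron weights (D2 weight
#'   must be negative and larger in magnitude than D1's is positive is not
#'   required; signs are enforced).
#' @param w_act_act mutual inhibition between action neurons (per action
#'   spike, applied to all other channels' action neurons); the
#'   winner-take-all competition of the selection circuit.
#' @param w_d2_d1,w_d1_d2 lateral inhibition weights (per presynaptic spike,
#'   applied to every SPN of the other type in the same channel); both must
#'   be <= 0 with |D2->D1| > |D1->D2|.
#' @param lat_cross_frac fraction of the lateral weight that also acts
#'   across channels (inhibition operates within and, more weakly, across
#'   channels).
#' @param sigma_spn,sigma_act per-step Gaussian membrane noise SD for SPNs
#'   and action neurons (the source of action exploration).
#' @param bg_act constant background drive to action neurons per step;
#'   holds them below threshold so noise can still trigger exploratory
#'   actions in channels with little learned input.
#' @param w_max plastic weight upper bound.
#' @param w_init constant initial value of all plastic weights.
#' @param ach_window cholinergic gate duration after an action spike (ms).
#' @param da_delay,da_duration dopamine pulse onset delay after the first
#'   counted action and pulse duration (ms; bookkeeping for logs).
#' @param da_amp_reward,da_amp_punish dopamine pulse amplitudes scaling the
#'   learning step for each valence.
#' @param dt simulation step (ms).
#' @return object of class \code{network_config}.
#' @export
network_config <- function(n_channels = 2L, n_d1 = 10L, n_d2 = 10L,
                           tau_m = 10, tau_m_act = 100,
                           v_th = 1, v_reset = 0, refractory = 2,
                           d2_excitability = 0.1,
                           w_d1_act = 0.02, w_d2_act = -0.03,
                           w_act_act = -2,
                           w_d2_d1 = -0.25, w_d1_d2 = -0.02,
                           lat_cross_frac = 0,
                           sigma_spn = 0.16, sigma_act = 0.0212,
                           bg_act = 0.007,
                           w_max = 4, w_init = 0.5,
                           ach_window = 150,
                           da_delay = 200, da_duration = 50,
                           da_amp_reward = 1, da_amp_punish = 1,
                           dt = 1) {
  cfg <- list(n_channels = as.integer(n_channels),
              n_d1 = as.integer(n_d1), n_d2 = as.integer(n_d2),
              tau_m = tau_m, tau_m_act = tau_m_act,
              v_th = v_th, v_reset = v_reset,
              refractory = refractory, d2_excitability = d2_excitability,
              w_d1_act = w_d1_act, w_d2_act = w_d2_act,
              w_act_act = w_act_act,
              w_d2_d1 = w_d2_d1, w_d1_d2 = w_d1_d2,
              lat_cross_frac = lat_cross_frac,
              sigma_spn = sigma_spn, sigma_act = sigma_act,
              bg_act = bg_act,
              w_max = w_max, w_init = w_init, ach_window = ach_window,
              da_delay = da_delay, da_duration = da_duration,
              da_amp_reward = da_amp_reward, da_amp_punish = da_amp_punish,
              dt = dt)
  class(cfg) <- "network_config"
  validate_network_config(cfg)
  cfg
}

validate_network_config <- function(cfg) {
  if (cfg$n_channels < 1L) stop("n_channels must be >= 1")
  if (cfg$n_d1 < 1L || cfg$n_d2 < 1L) stop("population sizes must be >= 1")
  if (cfg$tau_m <= 0 || cfg$dt <= 0) stop("time constants and dt must be > 0")
  if (cfg$v_th <= cfg$v_reset) stop("threshold must exceed reset")
  if (cfg$w_d1_act <= 0) stop("D1 -> action must be excitatory")
  if (cfg$w_d2_act >= 0) stop("D2 -> action must be inhibitory")
  if (cfg$w_act_act > 0) stop("action-action competition must be inhibitory")
  if (cfg$w_d2_d1 > 0 || cfg$w_d1_d2 > 0) stop("lateral weights are inhibitory")
  if (cfg$lat_cross_frac < 0 || cfg$lat_cross_frac > 1)
    stop("lat_cross_frac must lie in [0, 1]")
  if (abs(cfg$w_d2_d1) <= abs(cfg$w_d1_d2))
    stop("asymmetry violated: need |D2->D1| > |D1->D2|")
  if (cfg$w_max <= 0 || cfg$w_init < 0 || cfg$w_init > cfg$w_max)
    stop("need 0 <= w_init <= w_max")
  invisible(cfg)
}

#' Build the network state
#'
#' Instantiates the plastic cortico-striatal weight matrices (one per SPN
#' type, input x SPN, constant \code{w_init}) for a given input size, and
#' bundles them with the configuration. Dynamic state (membranes, traces,
#' gates) lives only inside a trial and is reset at trial boundaries; only
#' the weights persist across trials.
#'
#' @param config a \code{\link{network_config}}.
#' @param n_inputs total number of input neurons.
#' @return object of class \code{network_state} with elements \code{W1},
#'   \code{W2}, \code{config}, \code{n_inputs}.
#' @export
build_network <- function(config, n_inputs) {
  validate_network_config(config)
  if (n_inputs < 1L) stop("n_inputs must be >= 1")
  structure(list(
    W1 = matrix(config$w_init, n_inputs, config$n_channels * config$n_d1),
    W2 = matrix(config$w_init, n_inputs, config$n_channels * config$n_d2),
    config = config, n_inputs = as.integer(n_inputs)),
    class = "network_state")
}

#' Advance the network through a spike train (no plasticity)
#'
#' Low-level clock-driven stepping interface: integrates the circuit for
#' \code{n_steps} steps of \code{dt} under the given input spikes and
#' optional constant external currents, and returns all emitted spikes
#' tagged by population, plus gate intervals. Used directly for neuron-level
#' checks (f-I behaviour, excitability ordering); \code{\link{run_trial}}
#' wraps the same engine with adjudication and plasticity.
#'
#' @param state a \code{network_state}.
#' @param input_spikes data.frame with \code{time_ms}, \code{neuron_id}.
#' @param n_steps number of steps to simulate.
#' @param i_ext_d1,i_ext_d2,i_ext_act constant per-step external drive.
#' @param gated open ACh gates on action spikes (default TRUE).
#' @return list with \code{spikes} (time_ms, neuron_id, population:
#'   0 = D1, 1 = D2, 2 = action), \code{action_time}, \code{action_channel},
#'   \code{d1_count}, \code{d2_count}, \code{gates}.
#' @export
run_network <- function(state, input_spikes, n_steps,
                        i_ext_d1 = 0, i_ext_d2 = 0,
                        i_ext_act = state$config$bg_act,
                        gated = TRUE) {
  cfg <- state$config
  sp <- input_spikes[order(input_spikes$time_ms), , drop = FALSE]
  sim_trial_cpp(as.integer(floor(sp$time_ms / cfg$dt)),
                as.integer(sp$neuron_id),
                state$n_inputs, cfg$n_channels, cfg$n_d1, cfg$n_d2,
                state$W1, state$W2,
                cfg$tau_m, cfg$tau_m_act,
                cfg$v_th, cfg$v_th * (1 - cfg$d2_excitability),
                cfg$v_th, cfg$v_reset,
                as.integer(round(cfg$refractory / cfg$dt)),
                cfg$w_d1_act, cfg$w_d2_act, cfg$w_act_act,
                cfg$w_d2_d1, cfg$w_d1_d2,
                cfg$lat_cross_frac, cfg$sigma_spn, cfg$sigma_act,
                i_ext_d1, i_ext_d2, i_ext_act,
                as.integer(n_steps), cfg$dt,
                cfg$ach_window, gated,
                20, 20, FALSE, TRUE)
}

#' Open (or extend) a channel's ACh gate after an action spike
#'
#' Contract of the cholinergic pause abstraction: an action spike of channel
#' \code{c} at time \code{t} opens that channel's gate for
#' \code{(t, t + ach_window]}; a new spike while the gate is open extends
#' (does not stack) it. Other channels are untouched. The simulation engine
#' applies the same rule internally; this function is the reference
#' implementation used to reconstruct and check gate intervals from logs.
#'
#' @param gates data.frame with \code{channel}, \code{open}, \code{close}.
#' @param channel acting channel id (0-based).
#' @param t spike time (ms).
#' @param ach_window gate duration (ms).
#' @return updated gates data.frame.
#' @export
on_action_spike <- function(gates, channel, t, ach_window = 150) {
  if (is.null(gates))
    gates <- data.frame(channel = numeric(0), open = numeric(0),
                        close = numeric(0))
  k <- which(gates$channel == channel & gates$open < t & gates$close >= t)
  if (length(k)) {
    gates$close[[max(k)]] <- t + ach_window
  } else {
    gates <- rbind(gates, data.frame(channel = channel, open = t,
                                     close = t + ach_window))
  }
  gates
}

#' Schedule the dopamine pulse for an adjudicated outcome
#'
#' Rewarded trials schedule a global reward-tagged dopamine pulse at
#' \code{da_delay} ms after the first counted action; punished trials a
#' punishment-tagged pulse. No-response / premature-only trials deliver no
#' pulse. The pulse is global: every channel sees the same signal.
#'
#' @param outcome a \code{trial_outcome}.
#' @param config a \code{network_config}.
#' @return one-row data.frame (\code{time}, \code{duration},
#'   \code{amplitude}, \code{valence}) or NULL when no pulse is delivered.
#' @export
deliver_outcome <- function(outcome, config) {
  if (!outcome$rewarded && !outcome$punished) return(NULL)
  valence <- if (outcome$punished) "punish" else "reward"
  data.frame(time = outcome$latency_ms + config$da_delay,
             duration = config$da_duration,
             amplitude = if (valence == "reward") config$da_amp_reward
                         else config$da_amp_punish,
             valence = valence)
}

#' Simulate one full trial
#'
#' Runs the circuit for one episode: injects the trial's stimulus spikes,
#' collects action-neuron spikes (the first post-exclusion spike per channel
#' is that channel's single action event), adjudicates the outcome, delivers
#' the global dopamine pulse, and applies plasticity according to the
#' configured rule variant, followed by multiplicative postsynaptic LTD.
#' Membrane potentials, traces and gates are reset at trial boundaries; only
#' the weight matrices persist.
#'
#' @param state a \code{network_state}.
#' @param trial_spikes input spike log from
#'   \code{\link{generate_trial_spikes}}.
#' @param map current \code{stimulus_action_map}.
#' @param relevant_stimulus this trial's relevant stimulus id.
#' @param task a \code{task_config}.
#' @param plasticity a \code{\link{plasticity_config}}; use
#'   \code{learn = FALSE} to freeze weights.
#' @param episode episode index recorded in the outcome.
#' @param distractors distractor id set recorded in the outcome.
#' @param learn apply plasticity (default TRUE).
#' @param record_spikes return the full spike log (default FALSE).
#' @return list with \code{state} (updated weights), \code{outcome},
#'   \code{pulse}, \code{gates}, \code{d1_count}, \code{d2_count}, and
#'   (optionally) \code{spikes}, \code{eligibility}.
#' @export
run_trial <- function(state, trial_spikes, map, relevant_stimulus, task,
                      plasticity, episode = NA_integer_,
                      distractors = integer(0), learn = TRUE,
                      record_spikes = FALSE) {
  cfg <- state$config
  kern <- plasticity$kernels
  sp <- trial_spikes[order(trial_spikes$time_ms), , drop = FALSE]
  gated <- plasticity$mode == "da_ach_gated"
  res <- sim_trial_cpp(as.integer(floor(sp$time_ms / cfg$dt)),
                       as.integer(sp$neuron_id),
                       state$n_inputs, cfg$n_channels, cfg$n_d1, cfg$n_d2,
                       state$W1, state$W2,
                       cfg$tau_m, cfg$tau_m_act, cfg$v_th,
                       cfg$v_th * (1 - cfg$d2_excitability),
                       cfg$v_th, cfg$v_reset,
                       as.integer(round(cfg$refractory / cfg$dt)),
                       cfg$w_d1_act, cfg$w_d2_act, cfg$w_act_act,
                       cfg$w_d2_d1, cfg$w_d1_d2,
                       cfg$lat_cross_frac, cfg$sigma_spn, cfg$sigma_act,
                       0, 0, cfg$bg_act,
                       as.integer(round(task$trial_duration / cfg$dt)),
                       cfg$dt, cfg$ach_window, gated,
                       kern$tau_plus, kern$tau_minus,
                       learn, record_spikes)

  actions <- collapse_actions(res$action_channel, res$action_time,
                              task$exclusion_period)
  outcome <- evaluate_response(actions, map, relevant_stimulus, task,
                               episode = episode, distractors = distractors)
  pulse <- deliver_outcome(outcome, cfg)

  if (learn) {
    el1 <- list(prepost = res$E1_prepost, postpre = res$E1_postpre)
    el2 <- list(prepost = res$E2_prepost, postpre = res$E2_postpre)
    valence <- NULL
    eta <- plasticity$learning_rate
    if (plasticity$mode == "classic") {
      valence <- "reward"               # timing-only rule: always applied
    } else if (!is.null(pulse)) {
      valence <- pulse$valence
      eta <- eta * pulse$amplitude
    }
    if (!is.null(valence)) {
      cap <- if (valence == "punish") plasticity$dw_cap_punish
             else plasticity$dw_cap
      state$W1 <- apply_dopamine(state$W1, el1, "D1", valence, kern,
                                 eta, cfg$w_max, cap)
      state$W2 <- apply_dopamine(state$W2, el2, "D2", valence, kern,
                                 eta, cfg$w_max, cap)
    }
    state$W1 <- multiplicative_ltd(state$W1, res$d1_count,
                                   plasticity$lambda_ltd)
    state$W2 <- multiplicative_ltd(state$W2, res$d2_count,
                                   plasticity$lambda_ltd)
  }

  out <- list(state = state, outcome = outcome, pulse = pulse,
              gates = res$gates, d1_count = res$d1_count,
              d2_count = res$d2_count,
              action_time = res$action_time,
              action_channel = res$action_channel)
  if (record_spikes) out$spikes <- res$spikes
  if (learn) out$eligibility <- list(
    D1 = list(prepost = res$E1_prepost, postpre = res$E1_postpre),
    D2 = list(prepost = res$E2_prepost, postpre = res$E2_postpre))
  out
}

# First post-exclusion action spike per channel is the channel's action
# event; channels with only premature spikes contribute their first spike so
# the adjudicator can flag premature-only trials.
collapse_actions <- function(channel, time_ms, exclusion) {
  if (!length(channel))
    return(data.frame(channel = integer(0), time_ms = numeric(0)))
  df <- data.frame(channel = channel, time_ms = time_ms)
  out <- do.call(rbind, lapply(split(df, df$channel), function(d) {
    d <- d[order(d$time_ms), , drop = FALSE]
    counted <- d[d$time_ms >= exclusion, , drop = FALSE]
    if (nrow(counted)) counted[1L, ] else d[1L, ]
  }))
  out[order(out$time_ms), , drop = FALSE]
}
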