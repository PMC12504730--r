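#' STDP kernel specification
#'
#' One kernel per (SPN type, outcome valence) pair. Each kernel has a
#' pre-before-post amplitude \code{a_prepost} (weight change per coincidence
#' at \eqn{\Delta t = 0}, decaying as \eqn{\exp(-\Delta t/\tau_+)}) and a
#' post-before-pre amplitude \code{a_postpre} (decaying with \eqn{\tau_-}).
#' Sign conventions reflect pathway roles: D1 potentiates under reward and
#' depresses under punishment; D2 does the opposite, so punished channels
#' recruit indirect-pathway suppression.
#'
#' @param d1_reward,d1_punish,d2_reward,d2_punish length-2 numeric vectors
#'   \code{c(a_prepost, a_postpre)}.
#' @param tau_plus,tau_minus trace time constants in ms.
#' @return object of class \code{stdp_kernels}.
#' @export
stdp_kernels <- function(d1_reward = c(1, -0.5), d1_punish = c(-0.5, 0),
                         d2_reward = c(-0.3, 0), d2_punish = c(0.7, -0.5),
                         tau_plus = 20, tau_minus = 20) {
  stopifnot(tau_plus > 0, tau_minus > 0)
  if (d1_reward[[1L]] <= 0)
    stop("D1 reward pre-before-post amplitude must be positive (LTP)")
  k <- list(D1 = list(reward = d1_reward, punish = d1_punish),
            D2 = list(reward = d2_reward, punish = d2_punish),
            tau_plus = tau_plus, tau_minus = tau_minus)
  if (identical(k$D1, k$D2) || identical(k$D1$reward, k$D1$punish))
    stop("kernels must differ between SPN types and between valences")
  class(k) <- "stdp_kernels"
  k
}

#' One-step trace update
#'
#' Exponentially decaying spike traces: each trace decays by
#' \code{exp(-dt/tau)} per step and increments by 1 per spike of its neuron.
#'
#' @param traces list with numeric vectors \code{x_pre}, \code{y_post}.
#' @param pre_spikes,post_spikes integer indices (1-based) of neurons that
#'   spiked in this step (possibly empty, possibly repeated).
#' @param dt step in ms.
#' @param tau_plus,tau_minus decay constants in ms.
#' @return updated traces list.
#' @export
update_traces <- function(traces, pre_spikes, post_spikes, dt,
                          tau_plus = 20, tau_minus = 20) {
  stopifnot(dt > 0)
  traces$x_pre <- traces$x_pre * exp(-dt / tau_plus)
  traces$y_post <- traces$y_post * exp(-dt / tau_minus)
  for (i in pre_spikes) traces$x_pre[[i]] <- traces$x_pre[[i]] + 1
  for (j in post_spikes) traces$y_post[[j]] <- traces$y_post[[j]] + 1
  traces
}

#' Accumulate gated eligibility from spike trains
#'
#' Event-driven (exact) computation of the two coincidence sums that make up
#' the eligibility of one synapse population: for every postsynaptic spike,
#' the presynaptic trace is sampled and added to the pre-before-post
#' accumulator; for every presynaptic spike, the postsynaptic trace is added
#' to the post-before-pre accumulator. A pairing counts only if the later
#' spike of the pair falls inside an open ACh gate of the postsynaptic
#' neuron's channel. Simultaneous pre/post spikes count as pre-before-post.
#'
#' Kernel amplitudes are applied later, at dopamine delivery
#' (\code{\link{apply_dopamine}}); this function returns raw trace sums.
#'
#' @param pre list of numeric spike-time vectors, one per input neuron.
#' @param post list of numeric spike-time vectors, one per postsynaptic SPN.
#' @param post_channel integer vector, channel id (0-based) per SPN.
#' @param gates data.frame with columns \code{channel}, \code{open},
#'   \code{close}: gate open on \code{(open, close]}. Use \code{NULL} for
#'   ungated accumulation.
#' @param tau_plus,tau_minus trace time constants in ms.
#' @return list of matrices \code{prepost}, \code{postpre}
#'   (input x SPN).
#' @export
accumulate_eligibility <- function(pre, post, post_channel, gates,
                                   tau_plus = 20, tau_minus = 20) {
  n_in <- length(pre); n_post <- length(post)
  stopifnot(length(post_channel) == n_post)
  gate_open <- function(ch, t) {
    if (is.null(gates) || !nrow(gates)) return(is.null(gates))
    any(gates$channel == ch & t > gates$open & t <= gates$close)
  }
  ev <- rbind(
    do.call(rbind, c(list(data.frame(t = numeric(0), kind = integer(0), id = integer(0))),
      lapply(seq_len(n_in), function(i)
        if (length(pre[[i]])) data.frame(t = pre[[i]], kind = 0L, id = i) else NULL))),
    do.call(rbind, c(list(NULL),
      lapply(seq_len(n_post), function(j)
        if (length(post[[j]])) data.frame(t = post[[j]], kind = 1L, id = j) else NULL))))
  ev <- ev[order(ev$t, ev$kind), , drop = FALSE]  # pre before post at equal times
  x <- numeric(n_in); y <- numeric(n_post)
  t_last <- if (nrow(ev)) ev$t[[1L]] else 0
  E_pp <- matrix(0, n_in, n_post); E_qp <- matrix(0, n_in, n_post)
  for (r in seq_len(nrow(ev))) {
    dt <- ev$t[[r]] - t_last
    if (dt > 0) {
      x <- x * exp(-dt / tau_plus)
      y <- y * exp(-dt / tau_minus)
      t_last <- ev$t[[r]]
    }
    if (ev$kind[[r]] == 0L) {          # presynaptic spike
      i <- ev$id[[r]]
      ok <- vapply(seq_len(n_post),
                   function(j) gate_open(post_channel[[j]], ev$t[[r]]), logical(1))
      E_qp[i, ok] <- E_qp[i, ok] + y[ok]
      x[[i]] <- x[[i]] + 1
    } else {                            # postsynaptic spike
      j <- ev$id[[r]]
      if (gate_open(post_channel[[j]], ev$t[[r]]))
        E_pp[, j] <- E_pp[, j] + x
      y[[j]] <- y[[j]] + 1
    }
  }
  list(prepost = E_pp, postpre = E_qp)
}

#' Convert eligibility to a weight update under a dopamine pulse
#'
#' Implements the dopamine factor of the three-factor rule:
#' \deqn{\Delta w = \eta (A^{+}_{type,valence} E_{prepost} +
#'                        A^{-}_{type,valence} E_{postpre})}
#' Weights are clipped to \code{[0, w_max]}. The caller must discard
#' (zero) the eligibility after application; it is consumed by the pulse.
#'
#' @param weights weight matrix (input x SPN).
#' @param eligibility list with matrices \code{prepost}, \code{postpre}.
#' @param spn_type \code{"D1"} or \code{"D2"}.
#' @param valence \code{"reward"} or \code{"punish"}.
#' @param kernels a \code{\link{stdp_kernels}} object.
#' @param learning_rate step size \eqn{\eta} (scaled by the dopamine pulse
#'   amplitude upstream).
#' @param w_max upper weight bound.
#' @param dw_cap saturation bound on the per-synapse weight change of one
#'   pulse; keeps updates bounded when postsynaptic rates (and hence
#'   eligibility) are large.
#' @param soft_bound scale potentiation by \code{1 - w/w_max} (soft upper
#'   bound); depression stays weight-independent.
#' @return updated weight matrix.
#' @export
apply_dopamine <- function(weights, eligibility, spn_type, valence, kernels,
                           learning_rate, w_max, dw_cap = Inf,
                           soft_bound = TRUE) {
  if (!valence %in% c("reward", "punish")) stop("unknown valence tag: ", valence)
  if (!spn_type %in% c("D1", "D2")) stop("unknown SPN type: ", spn_type)
  a <- kernels[[spn_type]][[valence]]
  dw <- learning_rate *
    (a[[1L]] * eligibility$prepost + a[[2L]] * eligibility$postpre)
  if (is.finite(dw_cap)) dw <- pmin(pmax(dw, -dw_cap), dw_cap)
  if (soft_bound) dw <- ifelse(dw > 0, dw * (1 - weights / w_max), dw)
  pmin(pmax(weights + dw, 0), w_max)
}

#' Multiplicative postsynaptic LTD
#'
#' Homeostatic scaling applied once per trial: every weight onto
#' postsynaptic neuron \code{j} is scaled by
#' \code{1 - lambda * activity[j]}, floored at 0. This bounds weights: with
#' potentiation inflow \eqn{P} per trial and postsynaptic activity \eqn{r},
#' weights settle near the fixed point \eqn{w^* \approx P/(\lambda r)}.
#'
#' @param weights weight matrix (input x SPN).
#' @param post_activity non-negative per-SPN spike counts for the trial.
#' @param lambda decay coefficient per postsynaptic spike.
#' @return scaled weight matrix.
#' @export
multiplicative_ltd <- function(weights, post_activity, lambda) {
  stopifnot(lambda >= 0, all(post_activity >= 0),
            length(post_activity) == ncol(weights))
  f <- 1 - lambda * post_activity
  if (any(f < 0)) {
    warning("LTD factor clamped at 0 (lambda * activity > 1)")
    f <- pmax(f, 0)
  }
  sweep(weights, 2L, f, `*`)
}

#' Plasticity configuration, including rule variant
#'
#' Three rule variants are supported for the gating comparison:
#' \code{"classic"} (pure STDP: ungated, applied every trial with the reward
#' kernels regardless of outcome), \code{"reward_modulated"} (dopamine-
#' dependent but gate-free: global modulation) and \code{"da_ach_gated"}
#' (the full rule: eligibility accumulates only inside channel-local ACh
#' gate windows and is converted by the global dopamine pulse).
#'
#' @param mode one of \code{"classic"}, \code{"reward_modulated"},
#'   \code{"da_ach_gated"}.
#' @param learning_rate dopamine conversion step size \eqn{\eta}.
#' @param lambda_ltd multiplicative LTD coefficient per postsynaptic spike.
#' @param dw_cap per-pulse saturation bound on each synapse's weight change
#'   under a reward pulse.
#' @param dw_cap_punish the same bound under a punishment pulse; larger by
#'   default so that pruning of wrong associations outpaces their incidental
#'   reinforcement.
#' @param kernels a \code{\link{stdp_kernels}} object.
#' @return object of class \code{plasticity_config}.
#' @export
plasticity_config <- function(mode = "da_ach_gated", learning_rate = 0.05,
                              lambda_ltd = 1e-4, dw_cap = 0.1,
                              dw_cap_punish = 2 * dw_cap,
                              kernels = stdp_kernels()) {
  if (!mode %in% c("classic", "reward_modulated", "da_ach_gated"))
    stop("unknown plasticity mode: ", mode)
  stopifnot(learning_rate > 0, lambda_ltd >= 0, dw_cap > 0, dw_cap_punish > 0)
  structure(list(mode = mode, learning_rate = learning_rate,
                 lambda_ltd = lambda_ltd, dw_cap = dw_cap,
                 dw_cap_punish = dw_cap_punish,
                 kernels = kernels),
            class = "plasticity_config")
}
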