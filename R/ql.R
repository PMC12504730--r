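#' Tabular Q-learning baseline
#'
#' The comparison agent: a tabular Q-learner on the identical task schedule.
#' Because each episode presents one stimulus, takes one action and delivers
#' an immediate outcome, the task is a contextual bandit and the update
#' carries no discounted bootstrap term:
#' \deqn{Q(s,a) \leftarrow Q(s,a) + \alpha (r - Q(s,a))}
#'
#' @param n_stimuli number of stimuli (table rows).
#' @param n_actions number of actions (table columns).
#' @param alpha learning rate in (0, 1].
#' @param epsilon exploration probability in [0, 1].
#' @param r_reward,r_punish reward values for correct / incorrect actions.
#' @return object of class \code{q_table} (zero-initialized).
#' @export
q_table <- function(n_stimuli, n_actions, alpha = 0.1, epsilon = 0.1,
                    r_reward = 1, r_punish = -1) {
  stopifnot(n_stimuli >= 1, n_actions >= 1,
            alpha > 0, alpha <= 1, epsilon >= 0, epsilon <= 1)
  structure(list(q = matrix(0, n_stimuli, n_actions),
                 alpha = alpha, epsilon = epsilon,
                 r_reward = r_reward, r_punish = r_punish),
            class = "q_table")
}

#' Epsilon-greedy action selection
#'
#' With probability \code{epsilon} a uniformly random action; otherwise the
#' greedy action, ties broken uniformly at random.
#'
#' @param q a \code{\link{q_table}}.
#' @param stimulus stimulus id (0-based).
#' @return action id (0-based).
#' @export
select_action <- function(q, stimulus) {
  row <- q$q[stimulus + 1L, ]
  n <- length(row)
  if (q$epsilon > 0 && stats::runif(1) < q$epsilon) return(sample.int(n, 1L) - 1L)
  best <- which(row == max(row))
  if (length(best) == 1L) best - 1L else best[[sample.int(length(best), 1L)]] - 1L
}

#' Q-value update
#'
#' @param q a \code{\link{q_table}}.
#' @param stimulus,action ids (0-based).
#' @param reward scalar reward.
#' @return updated \code{q_table}.
#' @export
update_q <- function(q, stimulus, action, reward) {
  i <- stimulus + 1L; j <- action + 1L
  q$q[i, j] <- q$q[i, j] + q$alpha * (reward - q$q[i, j])
  q
}

#' Run the Q-learning agent on a task
#'
#' Uses the same schedule generator (and seed derivation) as the spiking
#' runs. Distractors are invisible to the tabular agent: the state is the
#' relevant stimulus. Correctness per episode is 1 when the selected action
#' matches the current mapping.
#'
#' @param task a \code{\link{task_config}}.
#' @param alpha,epsilon,r_reward,r_punish agent parameters.
#' @param n_seeds number of independent runs.
#' @param seed base seed; run k uses a seed derived from \code{seed + k}.
#' @return list with \code{correct} (episode x seed 0/1 matrix),
#'   \code{mean_accuracy} (per-episode mean over seeds), \code{q_final}
#'   (list of final tables).
#' @export
run_ql_experiment <- function(task, alpha = 0.1, epsilon = 0.1,
                              r_reward = 1, r_punish = -1,
                              n_seeds = 10L, seed = task$seed) {
  validate_task_config(task)
  n_ep <- task$n_episodes
  correct <- matrix(0L, n_ep, n_seeds)
  q_final <- vector("list", n_seeds)
  for (k in seq_len(n_seeds)) {
    set.seed(derive_seed(seed + k, 3L))
    sched <- schedule_trials(task)
    q <- q_table(task$n_relevant, task$n_channels, alpha, epsilon,
                 r_reward, r_punish)
    map <- stimulus_action_map(task)
    for (e in seq_len(n_ep)) {
      map <- apply_reversal(map, e, task)
      s <- sched$relevant_stimulus[[e]]
      a <- select_action(q, s)
      ok <- a == unname(map$mapping[as.character(s)])
      q <- update_q(q, s, a, if (ok) q$r_reward else q$r_punish)
      correct[e, k] <- as.integer(ok)
    }
    q_final[[k]] <- q
  }
  list(correct = correct, mean_accuracy = rowMeans(correct),
       q_final = q_final)
}
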