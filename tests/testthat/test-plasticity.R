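test_that("traces decay exponentially and sum over spikes", {
  tr <- list(x_pre = c(1, 0), y_post = 1)
  # pure decay over T = 40 ms in 1 ms steps
  for (i in 1:40) tr <- update_traces(tr, integer(0), integer(0), 1,
                                      tau_plus = 20, tau_minus = 20)
  expect_equal(tr$x_pre[1], exp(-2), tolerance = 1e-12)
  expect_equal(tr$y_post[1], exp(-2), tolerance = 1e-12)
  # one spike read out tau later
  tr <- list(x_pre = 0, y_post = 0)
  tr <- update_traces(tr, 1L, integer(0), 20, tau_plus = 20)
  tr <- update_traces(tr, integer(0), integer(0), 20, tau_plus = 20)
  expect_equal(tr$x_pre, exp(-1), tolerance = 1e-12)
  # spike train at {0, 5, 10} ms, tau = 20: trace at 10 ms matches direct sum
  tr <- list(x_pre = 0, y_post = 0)
  tr <- update_traces(tr, 1L, integer(0), 1e-9, tau_plus = 20)  # t = 0
  tr <- update_traces(tr, 1L, integer(0), 5, tau_plus = 20)     # t = 5
  tr <- update_traces(tr, 1L, integer(0), 5, tau_plus = 20)     # t = 10
  expect_equal(tr$x_pre, exp(-0.5) + exp(-0.25) + 1, tolerance = 1e-6)
})

test_that("trace-based eligibility equals brute-force pairwise sums", {
  set.seed(42)
  for (rep in 1:100) {
    n_in <- sample(1:3, 1); n_post <- sample(1:3, 1)
    pre <- lapply(seq_len(n_in), function(i) random_spike_train(sample(3:12, 1)))
    post <- lapply(seq_len(n_post), function(i) random_spike_train(sample(3:12, 1)))
    ch <- sample(0:1, n_post, replace = TRUE)
    gates <- if (rep %% 2 == 0)
      data.frame(channel = c(0, 1), open = c(50, 200), close = c(180, 360))
    else NULL                              # ungated half the time
    a <- accumulate_eligibility(pre, post, ch, gates)
    b <- brute_force_eligibility(pre, post, ch, gates)
    expect_equal(a$prepost, b$prepost, tolerance = 1e-9)
    expect_equal(a$postpre, b$postpre, tolerance = 1e-9)
  }
})

test_that("eligibility accrues only inside the postsynaptic channel's open gate", {
  pre <- list(100); post <- list(110)
  # pair inside an open gate of the right channel
  g <- data.frame(channel = 0, open = 90, close = 240)
  e <- accumulate_eligibility(pre, post, 0L, g)
  expect_equal(e$prepost[1, 1], exp(-10 / 20), tolerance = 1e-12)
  # same pair, gate open only in the other channel
  g1 <- data.frame(channel = 1, open = 90, close = 240)
  expect_identical(accumulate_eligibility(pre, post, 0L, g1)$prepost[1, 1], 0)
  # all gates closed for the whole trial
  g0 <- data.frame(channel = numeric(0), open = numeric(0), close = numeric(0))
  expect_identical(accumulate_eligibility(pre, post, 0L, g0)$prepost[1, 1], 0)
})

test_that("dopamine converts eligibility by the kernel closed form", {
  k <- stdp_kernels()
  e <- list(prepost = matrix(2.5), postpre = matrix(0))
  w <- matrix(1)
  # exact single-synapse closed form (no soft bound)
  w2 <- apply_dopamine(w, e, "D1", "reward", k, learning_rate = 0.1,
                       w_max = 10, soft_bound = FALSE)
  expect_equal(w2[1, 1], 1 + 0.1 * k$D1$reward[1] * 2.5, tolerance = 1e-12)
  # zero eligibility -> no change regardless of dopamine
  e0 <- list(prepost = matrix(0), postpre = matrix(0))
  expect_equal(apply_dopamine(w, e0, "D2", "punish", k, 0.5, 10), w)
  # clipping to [0, w_max]
  wl <- apply_dopamine(matrix(0.1), e, "D1", "punish", k, 10, 4,
                       soft_bound = FALSE)
  expect_equal(wl[1, 1], 0)
  expect_error(apply_dopamine(w, e, "D1", "neutral", k, 0.1, 10),
               "unknown valence")
  expect_error(stdp_kernels(d1_reward = c(-1, 0)), "positive")
})

test_that("multiplicative LTD has the predicted fixed point and scaling", {
  # zero weights stay zero
  expect_equal(multiplicative_ltd(matrix(0, 2, 2), c(5, 9), 0.01),
               matrix(0, 2, 2))
  # clamped factor warns
  expect_warning(multiplicative_ltd(matrix(1, 1, 1), 200, 0.01), "clamped")
  # constant potentiation P against activity r converges to ~P/(lambda r)
  sim_fix <- function(P, lambda, r, n = 2000) {
    w <- matrix(0)
    for (i in seq_len(n))
      w <- multiplicative_ltd(w + P, r, lambda)
    w[1, 1]
  }
  P <- 0.1; lambda <- 1e-4; r <- 100
  w_star <- sim_fix(P, lambda, r)
  expect_lt(abs(w_star - P / (lambda * r)) / (P / (lambda * r)), 0.02)
  # doubling lambda halves the asymptote
  expect_equal(sim_fix(P, 2 * lambda, r) / w_star, 0.5, tolerance = 0.02)
})

test_that("weight change requires all three factors (factorial)", {
  k <- stdp_kernels()
  gates_open <- data.frame(channel = 0, open = 0, close = 2000)
  gates_shut <- data.frame(channel = numeric(0), open = numeric(0),
                           close = numeric(0))
  pre_on <- list(c(100, 150, 300)); pre_off <- list(numeric(0))
  post_on <- list(c(120, 180)); post_off <- list(numeric(0))
  w0 <- matrix(1)
  dw <- function(pre, post, gates, da) {
    e <- accumulate_eligibility(pre, post, 0L, gates)
    if (!da) return(0)      # no pulse: apply_dopamine is never invoked
    w1 <- apply_dopamine(w0, e, "D1", "reward", k, 0.1, 10)
    w1[1, 1] - w0[1, 1]
  }
  expect_gt(dw(pre_on, post_on, gates_open, TRUE), 0)   # all factors present
  expect_identical(dw(pre_off, post_on, gates_open, TRUE), 0)  # no pre
  expect_identical(dw(pre_on, post_off, gates_open, TRUE), 0)  # no post
  expect_identical(dw(pre_on, post_on, gates_shut, TRUE), 0)   # gate closed
  expect_identical(dw(pre_on, post_on, gates_open, FALSE), 0)  # no dopamine
})

test_that("rule variants: classic is unmodulated, gated is channel-specific", {
  expect_error(plasticity_config(mode = "hebbian"), "unknown plasticity mode")
  task <- tiny_task()
  net <- network_config(2, sigma_spn = 0, sigma_act = 0, bg_act = 0,
                        w_d2_d1 = -1e-9, w_d1_d2 = 0)
  # engineered: stimulus 0 drives channel-0 D1; channel-1 populations silent
  mk_state <- function() {
    st <- build_network(net, 40)
    st$W1[] <- 0; st$W2[] <- 0
    st$W1[1:20, 1:10] <- 3
    st
  }
  pats <- make_stimulus_patterns(task)
  map <- stimulus_action_map(task)
  # classic STDP: weights change with spike timing alone, even unrewarded;
  # here the trial is rewarded/unrewarded irrelevant - compare against
  # da_ach_gated on an identical no-action trial later
  st <- mk_state()
  set.seed(51)
  spk <- generate_trial_spikes(pats[1])
  pl_classic <- plasticity_config(mode = "classic", lambda_ltd = 0)
  tr <- run_trial(st, spk, map, 0L, task, pl_classic)
  expect_false(isTRUE(all.equal(tr$state$W1, st$W1)))
  # channel specificity: channel-1 SPNs silent and never gated -> their
  # weight columns unchanged exactly after a full gated learning trial
  st <- mk_state()
  set.seed(51)
  spk <- generate_trial_spikes(pats[1])
  pl <- plasticity_config(lambda_ltd = 0)
  tr <- run_trial(st, spk, map, 0L, task, pl)
  expect_true(tr$outcome$rewarded)
  expect_identical(tr$state$W1[, 11:20], st$W1[, 11:20])
  expect_identical(tr$state$W2[, 11:20], st$W2[, 11:20])
  expect_false(isTRUE(all.equal(tr$state$W1[, 1:10], st$W1[, 1:10])))
})

test_that("engine eligibility matches the event-driven reference on a real trial", {
  task <- tiny_task()
  net <- network_config(2, sigma_spn = 0, sigma_act = 0, bg_act = 0,
                        w_d2_d1 = -1e-9, w_d1_d2 = 0)
  st <- build_network(net, 40)
  st$W1[] <- 0; st$W2[] <- 0
  st$W1[1:20, 1:10] <- 3
  st$W2[1:20, 1:10] <- 2
  pats <- make_stimulus_patterns(task)
  set.seed(77)
  spk <- generate_trial_spikes(pats[1])
  spk$time_ms <- floor(spk$time_ms)        # align to the 1 ms grid
  tr <- run_trial(st, spk, stimulus_action_map(task), 0L, task,
                  plasticity_config(), record_spikes = TRUE)
  d1 <- lapply(0:19, function(j)
    tr$spikes$time_ms[tr$spikes$population == 0 & tr$spikes$neuron_id == j])
  pre <- lapply(0:39, function(i) spk$time_ms[spk$neuron_id == i])
  ref <- accumulate_eligibility(pre, d1, rep(0:1, each = 10), tr$gates)
  expect_equal(unname(tr$eligibility$D1$prepost), ref$prepost,
               tolerance = 1e-9)
  expect_equal(unname(tr$eligibility$D1$postpre), ref$postpre,
               tolerance = 1e-9)
})
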