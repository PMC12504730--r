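quiet_net <- function(...) {
  network_config(n_channels = 2, sigma_spn = 0, sigma_act = 0, bg_act = 0,
                 w_d2_d1 = -1e-9, w_d1_d2 = 0, ...)
}

test_that("build_network wires channels with the stated asymmetries", {
  cfg <- network_config(2)
  st <- build_network(cfg, 40)
  expect_equal(dim(st$W1), c(40, 2 * cfg$n_d1))
  expect_equal(dim(st$W2), c(40, 2 * cfg$n_d2))
  expect_true(all(st$W1 == cfg$w_init) && all(st$W2 == cfg$w_init))
  expect_gt(abs(cfg$w_d2_d1), abs(cfg$w_d1_d2))
  expect_gt(cfg$w_d1_act, 0)
  expect_lt(cfg$w_d2_act, 0)
  expect_error(network_config(0), "n_channels")
  expect_error(network_config(2, n_d1 = 0), "population")
  expect_error(network_config(2, w_d2_d1 = -0.01, w_d1_d2 = -0.02),
               "asymmetry")
})

test_that("resting network without input or noise stays silent", {
  st <- build_network(quiet_net(), 40)
  r <- run_network(st, data.frame(time_ms = numeric(0), neuron_id = integer(0)),
                   500, i_ext_act = 0)
  expect_identical(nrow(r$spikes), 0L)
  expect_identical(sum(r$d1_count) + sum(r$d2_count), 0L)
})

test_that("constant drive reproduces the analytic LIF f-I interspike interval", {
  st <- build_network(quiet_net(n_d1 = 1, n_d2 = 1), 4)
  cfg <- st$config
  for (I in c(0.15, 0.25, 0.5)) {
    r <- run_network(st, data.frame(time_ms = numeric(0), neuron_id = integer(0)),
                     4000, i_ext_d1 = I, i_ext_act = 0)
    d1_times <- r$spikes$time_ms[r$spikes$population == 0 &
                                 r$spikes$neuron_id == 0]
    expect_gt(length(d1_times), 5)
    isi_sim <- stats::median(diff(d1_times))
    v_inf <- I * cfg$tau_m
    t_cont <- cfg$tau_m * log(v_inf / (v_inf - cfg$v_th)) + cfg$refractory
    expect_lt(abs(isi_sim - t_cont), 1 + 1e-9)   # within one dt of closed form
  }
})

test_that("D2 SPNs are at least as excitable as D1 across a drive grid", {
  st <- build_network(quiet_net(), 40)
  for (I in c(0.12, 0.2, 0.3, 0.6)) {
    r <- run_network(st, data.frame(time_ms = numeric(0), neuron_id = integer(0)),
                     2000, i_ext_d1 = I, i_ext_d2 = I, i_ext_act = 0)
    expect_gte(sum(r$d2_count), sum(r$d1_count))
  }
})

test_that("action spikes open channel-local refreshing ACh gates", {
  # refresh semantics of the reference rule
  g <- on_action_spike(NULL, 1, 900)
  expect_equal(g$close, 1050)
  g <- on_action_spike(g, 1, 950)           # refresh extends, not stacks
  expect_identical(nrow(g), 1L)
  expect_equal(g$close, 1100)
  g <- on_action_spike(g, 0, 960)           # other channel independent
  expect_identical(nrow(g), 2L)
  expect_equal(g$close[g$channel == 0], 1110)
  g2 <- on_action_spike(g, 1, 1500)         # expired gate -> new interval
  expect_identical(nrow(g2), 3L)

  # engine gates agree with folding the reference rule over action spikes,
  # and are local to the acting channel
  task <- tiny_task()
  net <- quiet_net()
  st <- build_network(net, 40)
  st$W1[1:20, 1:10] <- 3                    # stimulus 0 drives channel 0 only
  pats <- make_stimulus_patterns(task)
  set.seed(31)
  spk <- generate_trial_spikes(pats[1])
  r <- run_network(st, spk, 2000, i_ext_act = 0)
  expect_gt(length(r$action_time), 0)
  expect_true(all(r$action_channel == 0))
  expect_true(all(r$gates$channel == 0))
  ref <- NULL
  for (k in seq_along(r$action_time))
    ref <- on_action_spike(ref, r$action_channel[k], r$action_time[k],
                           net$ach_window)
  expect_equal(r$gates$open, ref$open)
  expect_equal(r$gates$close, ref$close)
  # gate locality invariant: every gate opening coincides with an action spike
  for (k in seq_len(nrow(r$gates)))
    expect_true(any(r$action_channel == r$gates$channel[k] &
                    abs(r$action_time - r$gates$open[k]) < 1e-9))
})

test_that("dopamine pulses are outcome-tagged, global and absent without outcome", {
  cfg <- network_config(2)
  rewarded <- structure(list(rewarded = TRUE, punished = FALSE,
                             latency_ms = 700), class = "trial_outcome")
  p <- deliver_outcome(rewarded, cfg)
  expect_identical(p$valence, "reward")
  expect_equal(p$time, 700 + cfg$da_delay)
  punished <- structure(list(rewarded = FALSE, punished = TRUE,
                             latency_ms = 400), class = "trial_outcome")
  expect_identical(deliver_outcome(punished, cfg)$valence, "punish")
  none <- structure(list(rewarded = FALSE, punished = FALSE,
                         latency_ms = NA_real_), class = "trial_outcome")
  expect_null(deliver_outcome(none, cfg))
})

test_that("run_trial selects the channel with engineered strong weights", {
  task <- tiny_task()
  st <- build_network(quiet_net(), 40)
  st$W1[1:20, 1:10] <- 3
  st$W1[, 11:20] <- 0
  map <- stimulus_action_map(task)
  pats <- make_stimulus_patterns(task)
  set.seed(21)
  spk <- generate_trial_spikes(pats[1])
  tr <- run_trial(st, spk, map, 0L, task, plasticity_config(), learn = FALSE)
  expect_identical(tr$outcome$action, 0L)
  expect_true(tr$outcome$rewarded)
})

test_that("identical seed reproduces identical trials and weights stay bounded", {
  task <- tiny_task()
  net <- network_config(2)
  run_once <- function() {
    st <- build_network(net, 40)
    pats <- make_stimulus_patterns(task)
    set.seed(99)
    outs <- list()
    for (i in 1:5) {
      spk <- generate_trial_spikes(pats[1])
      tr <- run_trial(st, spk, map = stimulus_action_map(task), 0L, task,
                      plasticity_config(), record_spikes = TRUE)
      st <- tr$state
      outs[[i]] <- tr
    }
    outs
  }
  a <- run_once(); b <- run_once()
  for (i in 1:5) {
    expect_identical(a[[i]]$spikes, b[[i]]$spikes)
    expect_identical(a[[i]]$outcome, b[[i]]$outcome)
    expect_identical(a[[i]]$state$W1, b[[i]]$state$W1)
    w1 <- a[[i]]$state$W1; w2 <- a[[i]]$state$W2
    expect_true(all(w1 >= 0 & w1 <= net$w_max))
    expect_true(all(w2 >= 0 & w2 <= net$w_max))
  }
})
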