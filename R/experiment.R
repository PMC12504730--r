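#' Experiment presets
#'
#' The study's experimental settings: baseline association learning, credit
#' assignment under distractors, single and repeated contingency reversals,
#' and the action-space scaling comparison against tabular Q-learning.
#' Fields: \code{name}, \code{task} (a \code{\link{task_config}}),
#' \code{agent} ("snn" or "ql"), \code{mode} (plasticity rule variant),
#' \code{n_seeds}, and optionally \code{grid} (a named list of task fields
#' to sweep).
#'
#' @return named list of presets.
#' @export
experiment_presets <- function() {
  list(
    baseline = list(
      name = "baseline", agent = "snn", mode = "da_ach_gated", n_seeds = 1L,
      task = task_config(n_channels = 2L, n_relevant = 2L, n_distractors = 0L,
                         n_episodes = 10000L)),
    credit_assignment = list(
      name = "credit_assignment", agent = "snn", mode = "da_ach_gated",
      n_seeds = 100L,
      grid = list(n_distractors = 0:8),
      task = task_config(n_channels = 2L, n_relevant = 2L, n_distractors = 8L,
                         n_episodes = 10000L)),
    reversal_single = list(
      name = "reversal_single", agent = "snn", mode = "da_ach_gated",
      n_seeds = 50L,
      task = task_config(n_channels = 2L, n_relevant = 2L, n_distractors = 8L,
                         n_episodes = 2000L, reversal_episodes = 500L)),
    reversal_repeated = list(
      name = "reversal_repeated", agent = "snn", mode = "da_ach_gated",
      n_seeds = 1L,
      task = task_config(n_channels = 2L, n_relevant = 2L, n_distractors = 8L,
                         n_episodes = 10000L,
                         reversal_episodes = c(2000L, 4000L, 6000L, 8000L))),
    scaling = list(
      name = "scaling", agent = "both", mode = "da_ach_gated", n_seeds = 20L,
      grid = list(n_actions = c(4L, 8L, 16L, 32L)),
      task = task_config(n_channels = 4L, n_relevant = 4L, n_distractors = 0L,
                         n_episodes = 10000L)))
}

#' Downscale a preset
#'
#' Returns a copy of the preset with fewer episodes and/or seeds, for quick
#' runs; all other fields unchanged.
#'
#' @param preset a preset from \code{\link{experiment_presets}} or
#'   \code{\link{load_config}}.
#' @param n_episodes,n_seeds replacement values (NULL keeps the original).
#' @return modified preset.
#' @export
scale_preset <- function(preset, n_episodes = NULL, n_seeds = NULL) {
  if (!is.null(n_episodes)) {
    preset$task$n_episodes <- as.integer(n_episodes)
    preset$task$reversal_episodes <-
      preset$task$reversal_episodes[preset$task$reversal_episodes < n_episodes]
    validate_task_config(preset$task)
  }
  if (!is.null(n_seeds)) preset$n_seeds <- as.integer(n_seeds)
  preset
}

preset_fields <- c("name", "agent", "mode", "n_seeds", "task", "grid")
task_fields <- c("n_channels", "n_relevant", "n_distractors",
                 "trial_duration", "exclusion_period", "n_episodes",
                 "reversal_episodes", "pop_size", "rate_active", "n_blocks",
                 "seed")

#' Load experiment presets from a YAML config file
#'
#' The file holds one section per preset; each section may give any subset
#' of the task fields (missing ones take \code{\link{task_config}} defaults)
#' plus \code{agent}, \code{mode}, \code{n_seeds} and \code{grid}. Unknown
#' keys are rejected. See \code{system.file("extdata", "presets.yaml",
#' package = "striatumgate")} for the bundled experiment definitions.
#'
#' @param path YAML file path.
#' @return named list of validated presets.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)) || any(names(raw) == ""))
    stop("config must map preset names to sections")
  out <- lapply(names(raw), function(nm) {
    sec <- raw[[nm]]
    bad <- setdiff(names(sec), c(preset_fields[-5L], task_fields))
    if (length(bad))
      stop("unknown config keys in preset '", nm, "': ",
           paste(bad, collapse = ", "))
    tf <- sec[intersect(names(sec), task_fields)]
    task <- do.call(task_config, tf)
    list(name = nm,
         agent = sec$agent %||% "snn",
         mode = sec$mode %||% "da_ach_gated",
         n_seeds = as.integer(sec$n_seeds %||% 1L),
         grid = sec$grid,
         task = task)
  })
  names(out) <- names(raw)
  for (p in out) {
    if (!p$agent %in% c("snn", "ql", "both")) stop("unknown agent: ", p$agent)
    if (!p$mode %in% c("classic", "reward_modulated", "da_ach_gated"))
      stop("unknown plasticity mode: ", p$mode)
  }
  out
}

#' Serialize presets back to YAML
#'
#' Round-trip companion of \code{\link{load_config}}:
#' \code{load_config(dump_config(p, f))} reproduces \code{p}.
#'
#' @param presets named list of presets.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
dump_config <- function(presets, path) {
  norm <- lapply(presets, function(p) {
    sec <- c(list(agent = p$agent, mode = p$mode, n_seeds = p$n_seeds),
             unclass(p$task))
    if (!is.null(p$grid)) sec$grid <- p$grid
    sec[!vapply(sec, function(x) is.null(x) || length(x) == 0L, logical(1))]
  })
  yaml::write_yaml(norm, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(x), f)
  unname(tools::md5sum(f))
}

#' Run an experiment preset and serialize its artifacts
#'
#' Runs every (grid point x seed) combination and writes, per run, an
#' outcome CSV (one row per episode: episode, relevant_stimulus, action,
#' latency_ms, rewarded, punished, premature_only, epoch, d1_spikes,
#' d2_spikes) and a weight-snapshot CSV (block means per episode x stimulus
#' x channel), plus a manifest (config digest, seeds, package version).
#' Existing runs whose manifest digest matches are skipped, so interrupted
#' experiments resume per seed; a digest mismatch fails loudly.
#'
#' @param preset a preset (see \code{\link{experiment_presets}}).
#' @param out_dir output directory (created).
#' @param network_args named list of \code{\link{network_config}} overrides.
#' @param snapshot_every weight snapshot cadence in episodes.
#' @return \code{out_dir}, invisibly.
#' @export
run_experiment <- function(preset, out_dir, network_args = list(),
                           snapshot_every = 10L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- expand_grid_points(preset)
  digest <- config_digest(list(preset = preset[setdiff(names(preset), "task")],
                               task = unclass(preset$task),
                               network = network_args))
  man_path <- file.path(out_dir, "manifest.json")
  if (file.exists(man_path)) {
    old <- jsonlite::read_json(man_path)
    if (!identical(old$digest, digest))
      stop("out_dir holds results for a different configuration; ",
           "refusing to mix (", out_dir, ")")
  }
  for (g in grid) {
    task <- g$task
    tag <- g$tag
    for (k in seq_len(preset$n_seeds)) {
      seed <- task$seed + k - 1L
      stem <- file.path(out_dir, sprintf("%sseed%03d", tag, seed))
      oc_file <- paste0(stem, "_outcomes.csv")
      if (file.exists(oc_file)) next  # resume
      if (preset$agent %in% c("snn", "both")) {
        net <- do.call(network_config,
                       c(list(n_channels = task$n_channels), network_args))
        run <- run_snn_experiment(task, net,
                                  plasticity_config(mode = preset$mode),
                                  seed = seed,
                                  snapshot_every = snapshot_every)
        utils::write.csv(run$outcomes, oc_file, row.names = FALSE)
        if (!is.null(run$snapshots))
          utils::write.csv(run$snapshots, paste0(stem, "_weights.csv"),
                           row.names = FALSE)
      }
      if (preset$agent %in% c("ql", "both")) {
        ql <- run_ql_experiment(task, n_seeds = 1L, seed = seed)
        utils::write.csv(data.frame(episode = seq_len(task$n_episodes),
                                    correct = ql$correct[, 1L]),
                         paste0(stem, "_ql.csv"), row.names = FALSE)
      }
    }
  }
  jsonlite::write_json(
    list(preset = preset$name, digest = digest,
         n_seeds = preset$n_seeds,
         seeds = preset$task$seed + seq_len(preset$n_seeds) - 1L,
         version = as.character(utils::packageVersion("striatumgate"))),
    man_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

expand_grid_points <- function(preset) {
  if (is.null(preset$grid)) {
    return(list(list(task = preset$task, tag = "")))
  }
  key <- names(preset$grid)[[1L]]
  lapply(preset$grid[[1L]], function(v) {
    task <- preset$task
    if (key == "n_actions") {
      task$n_channels <- as.integer(v)
      task$n_relevant <- as.integer(v)
    } else {
      task[[key]] <- as.integer(v)
    }
    validate_task_config(task)
    list(task = task, tag = sprintf("%s%02d_", key, v))
  })
}

#' Summarize an experiment bundle into headline statistics
#'
#' Reads the CSV artifacts written by \code{\link{run_experiment}} and
#' computes the statistics appropriate to the bundle's preset: accuracy
#' curves and weight contrasts for learning runs, reversal statistics
#' (paired t, Cohen's d, remap time, D2/D1 ratio) when the task contains
#' reversals, and per-N power-law fits for scaling bundles. The summary is
#' written to \code{summary.json} in the bundle and returned.
#'
#' @param out_dir bundle directory.
#' @param preset the preset the bundle was produced from.
#' @return named list of statistics, invisibly.
#' @export
report <- function(out_dir, preset) {
  files <- list.files(out_dir, "_outcomes\\.csv$", full.names = TRUE)
  ql_files <- list.files(out_dir, "_ql\\.csv$", full.names = TRUE)
  if (!length(files) && !length(ql_files))
    stop("no outcome files found in ", out_dir)
  out <- list(preset = preset$name)
  if (length(files)) {
    runs <- lapply(files, utils::read.csv)
    wfiles <- sub("_outcomes\\.csv$", "_weights.csv", files)
    snaps <- lapply(wfiles, function(f)
      if (file.exists(f)) utils::read.csv(f) else NULL)
    acc <- rowMeans(vapply(runs, function(r) as.numeric(r$rewarded),
                           numeric(nrow(runs[[1L]]))))
    out$final_accuracy_pct <- 100 * mean(utils::tail(
      smooth_accuracy(acc), 50L))
    rev <- preset$task$reversal_episodes
    if (length(rev) && !any(vapply(snaps, is.null, logical(1)))) {
      rs <- reversal_statistics(runs, snaps, preset$task, rev[[1L]])
      out <- c(out, rs)
    }
  }
  if (length(ql_files)) {
    tag <- sub("seed[0-9]+_ql\\.csv$", "", basename(ql_files))
    for (g in unique(tag)) {
      ql <- lapply(ql_files[tag == g], utils::read.csv)
      acc <- rowMeans(vapply(ql, function(r) as.numeric(r$correct),
                             numeric(nrow(ql[[1L]]))))
      sm <- smooth_accuracy(acc)
      key <- if (g == "") "ql" else paste0("ql_", sub("_$", "", g))
      out[[paste0(key, "_final_accuracy_pct")]] <-
        100 * mean(utils::tail(sm, 50L))
      fit <- try(powerlaw_fit(sm), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        out[[paste0(key, "_powerlaw_slope")]] <- fit$slope
        out[[paste0(key, "_powerlaw_r2")]] <- fit$r_squared
      }
    }
  }
  jsonlite::write_json(out, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Reversal statistics across simulations
#'
#' For a set of single-reversal runs, computes: mean D1-D2 weight of
#' correct stimulus-action pairs vs distractor pairs just before the
#' reversal (paired t, Cohen's d_z); the post- vs pre-reversal D2/D1
#' activity ratio (100-episode windows excluding the reversal episode,
#' paired t); the behavioural remap time (episodes until smoothed reward
#' rate re-reaches its pre-reversal level minus 5 points); and the final
#' newly-correct vs previously-correct weights.
#'
#' @param runs list of per-run outcome data.frames (as written by
#'   \code{\link{run_experiment}} or from \code{run_snn_experiment()$outcomes}).
#' @param snaps list of per-run snapshot data.frames.
#' @param task the \code{task_config} used.
#' @param reversal_episode the reversal episode.
#' @param ratio_window window width in episodes for the activity ratio.
#' @return named list of statistics.
#' @export
reversal_statistics <- function(runs, snaps, task, reversal_episode,
                                ratio_window = 100L) {
  n_rel <- task$n_relevant
  distr <- if (task$n_distractors > 0L)
    seq.int(n_rel, length.out = task$n_distractors) else integer(0)
  map0 <- stimulus_action_map(task)
  map1 <- apply_reversal(map0, reversal_episode,
                         within_reversals(task, reversal_episode))
  pair_mean <- function(snap, ep, map, stimuli) {
    s <- snap[snap$episode == ep, ]
    mean(vapply(stimuli, function(st)
      s$diff[s$stimulus == st &
             s$channel == unname(map$mapping[as.character(st)])],
      numeric(1)))
  }
  distractor_mean <- function(snap, ep) {
    s <- snap[snap$episode == ep, ]
    mean(s$diff[s$stimulus %in% distr])
  }
  pre_ep <- max(snaps[[1L]]$episode[snaps[[1L]]$episode < reversal_episode])
  end_ep <- max(snaps[[1L]]$episode)
  rel_ids <- seq_len(n_rel) - 1L

  correct_pre <- vapply(snaps, pair_mean, numeric(1),
                        ep = pre_ep, map = map0, stimuli = rel_ids)
  distr_pre <- vapply(snaps, distractor_mean, numeric(1), ep = pre_ep)
  new_final <- vapply(snaps, pair_mean, numeric(1),
                      ep = end_ep, map = map1, stimuli = rel_ids)
  old_final <- vapply(snaps, pair_mean, numeric(1),
                      ep = end_ep, map = map0, stimuli = rel_ids)

  win_pre <- seq.int(reversal_episode - ratio_window, reversal_episode - 1L)
  win_post <- seq.int(reversal_episode + 1L,
                      reversal_episode + ratio_window)
  ratio_pre <- vapply(runs, function(r)
    d2_d1_ratio(r$d1_spikes, r$d2_spikes, win_pre), numeric(1))
  ratio_post <- vapply(runs, function(r)
    d2_d1_ratio(r$d1_spikes, r$d2_spikes, win_post), numeric(1))

  remap <- vapply(runs, function(r) {
    sm <- smooth_accuracy(100 * as.numeric(r$rewarded))
    as.numeric(remap_time(sm, reversal_episode)$episodes)
  }, numeric(1))

  st_pre <- if (length(runs) >= 2L) paired_stats(correct_pre, distr_pre)
            else list(t = NA, p = NA, d = NA)
  st_ratio <- if (length(runs) >= 2L) paired_stats(ratio_pre, ratio_post)
              else list(t = NA, p = NA, d = NA)
  st_final <- if (length(runs) >= 2L) paired_stats(new_final, old_final)
              else list(t = NA, p = NA, d = NA)

  list(n_sims = length(runs),
       correct_weight_pre = mean(correct_pre),
       correct_weight_pre_sd = stats::sd(correct_pre),
       distractor_weight_pre = mean(distr_pre),
       distractor_weight_pre_sd = stats::sd(distr_pre),
       t_pre = st_pre$t, p_pre = st_pre$p, d_pre = st_pre$d,
       d2d1_ratio_pre = mean(ratio_pre, na.rm = TRUE),
       d2d1_ratio_post = mean(ratio_post, na.rm = TRUE),
       t_ratio = st_ratio$t, p_ratio = st_ratio$p,
       remap_mean = mean(remap, na.rm = TRUE),
       remap_sd = stats::sd(remap, na.rm = TRUE),
       remap_recovered = sum(is.finite(remap)),
       new_correct_final = mean(new_final),
       new_correct_final_sd = stats::sd(new_final),
       old_correct_final = mean(old_final),
       old_correct_final_sd = stats::sd(old_final),
       t_final = st_final$t, p_final = st_final$p, d_final = st_final$d)
}

# task copy whose reversal list contains the given episode (so
# apply_reversal fires when reconstructing mapping epochs)
within_reversals <- function(task, episode) {
  task$reversal_episodes <- as.integer(episode)
  task
}

#' Diagonal-contrast of the learned D1 weight matrix
#'
#' Mean D1 block weight of correct (diagonal) relevant stimulus-channel
#' pairs vs incorrect (off-diagonal) ones, under the current mapping.
#'
#' @param run result of \code{\link{run_snn_experiment}}.
#' @return list with \code{diag}, \code{offdiag}, \code{ratio}.
#' @export
gating_contrast <- function(run) {
  task <- run$task
  sp <- stimulus_partition(task)
  cp <- list(D1 = channel_partition(run$network$n_channels, run$network$n_d1),
             D2 = channel_partition(run$network$n_channels, run$network$n_d2))
  ws <- weight_summary(run$W1, run$W2, sp, cp)
  rel <- seq_len(task$n_relevant)
  correct <- unname(run$map$mapping[as.character(rel - 1L)]) + 1L
  idx <- cbind(rel, correct)
  diag_mean <- mean(ws$d1[idx])
  off <- ws$d1[rel, , drop = FALSE]
  off[idx] <- NA
  offdiag_mean <- mean(off, na.rm = TRUE)
  list(diag = diag_mean, offdiag = offdiag_mean,
       ratio = diag_mean / max(offdiag_mean, 1e-12))
}
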