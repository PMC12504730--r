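#' Gaussian smoothing of an accuracy series
#'
#' Convolution with a normalized Gaussian kernel (sigma in episode units,
#' truncated at 4 sigma) under reflective boundary handling; output length
#' equals input length.
#'
#' @param x numeric series (e.g. 0/1 correctness or percentages).
#' @param sigma kernel SD in episodes (default 10).
#' @return smoothed numeric series.
#' @export
smooth_accuracy <- function(x, sigma = 10) {
  if (sigma <= 0) stop("sigma must be > 0")
  n <- length(x)
  if (n < 1L) stop("series must have length >= 1")
  r <- min(ceiling(4 * sigma), n - 1L)
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  if (r == 0L) return(x)
  xp <- c(x[seq.int(r + 1L, 2L)], x, x[seq.int(n - 1L, n - r)])
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[seq.int(r + 1L, r + n)])
}

#' Block-mean weight summary per stimulus and channel
#'
#' Averages each plastic weight matrix over (stimulus input population x
#' channel SPN population) blocks, and reports the D1 - D2 difference.
#'
#' @param W1,W2 weight matrices (input x SPN) for D1 and D2.
#' @param stimulus_partition list of 1-based row-index vectors per stimulus.
#' @param channel_partition list with elements \code{D1} and \code{D2}, each
#'   a list of 1-based column-index vectors per channel.
#' @return list of (stimulus x channel) matrices \code{d1}, \code{d2},
#'   \code{diff} with \code{diff = d1 - d2} exactly.
#' @export
weight_summary <- function(W1, W2, stimulus_partition, channel_partition) {
  ns <- length(stimulus_partition)
  nc <- length(channel_partition$D1)
  block <- function(W, rows, cols) {
    if (!length(rows) || !length(cols)) stop("empty partition block")
    mean(W[rows, cols, drop = FALSE])
  }
  d1 <- matrix(0, ns, nc); d2 <- matrix(0, ns, nc)
  for (s in seq_len(ns)) for (c in seq_len(nc)) {
    d1[s, c] <- block(W1, stimulus_partition[[s]], channel_partition$D1[[c]])
    d2[s, c] <- block(W2, stimulus_partition[[s]], channel_partition$D2[[c]])
  }
  list(d1 = d1, d2 = d2, diff = d1 - d2)
}

#' Power-law fit of a learning curve in the low-accuracy regime
#'
#' Ordinary least squares of log10(accuracy) on log10(episode), restricted
#' to episodes whose accuracy lies below the threshold (the regime where
#' learning curves are near power laws; the default threshold 0.79
#' corresponds to log10(accuracy) < -0.1).
#'
#' @param accuracy per-episode accuracy as a fraction in (0, 1], typically
#'   seed-averaged and smoothed. Zeros are floored at \code{zero_floor}
#'   before taking logs.
#' @param episodes episode axis (default \code{seq_along(accuracy)}).
#' @param threshold regime cutoff (default 0.79).
#' @param zero_floor replacement for zero accuracies (default \code{NULL}:
#'   zeros excluded from the fit).
#' @return object of class \code{powerlaw_fit}: list with \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{mask}, \code{n_points}.
#' @export
powerlaw_fit <- function(accuracy, episodes = seq_along(accuracy),
                         threshold = 0.79, zero_floor = NULL) {
  stopifnot(length(accuracy) == length(episodes))
  acc <- accuracy
  if (!is.null(zero_floor)) acc[acc <= 0] <- zero_floor
  mask <- is.finite(acc) & acc > 0 & acc < threshold & episodes >= 1
  if (sum(mask) < 3L)
    stop("need at least 3 points below the accuracy threshold")
  fit <- stats::lm(log10(acc[mask]) ~ log10(episodes[mask]))
  structure(list(slope = unname(stats::coef(fit)[[2L]]),
                 intercept = unname(stats::coef(fit)[[1L]]),
                 r_squared = summary(fit)$r.squared,
                 mask = mask, n_points = sum(mask)),
            class = "powerlaw_fit")
}

#' Paired t-test with Cohen's d (d_z)
#'
#' Paired t on the differences \code{a - b}; the effect size is the paired
#' (within-subject) Cohen's d, \eqn{d_z = \bar{d}/s_d = t/\sqrt{n}}.
#' Identical samples return t = 0, d = 0, p = 1; zero-variance differences
#' with nonzero mean are an error.
#'
#' @param a,b equal-length numeric vectors (one value per simulation).
#' @return list with \code{t}, \code{dof}, \code{p}, \code{d}, \code{n},
#'   \code{mean_diff}.
#' @export
paired_stats <- function(a, b) {
  n <- length(a)
  stopifnot(length(b) == n, n >= 2)
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (all(d == 0))
      return(list(t = 0, dof = n - 1L, p = 1, d = 0, n = n, mean_diff = 0))
    stop("zero variance of differences")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), dof = unname(tt$parameter),
       p = tt$p.value, d = mean(d) / sdd, n = n, mean_diff = mean(d))
}

#' Paired Cohen's d from a t statistic
#'
#' The identity \eqn{d_z = t/\sqrt{n}} for the paired formulation.
#' @param t paired t statistic.
#' @param n number of pairs.
#' @return d_z.
#' @export
d_from_t <- function(t, n) t / sqrt(n)

#' Episodes needed to re-reach criterion accuracy after a reversal
#'
#' The criterion defaults to the mean smoothed accuracy over the
#' \code{pre_window} episodes preceding the reversal, minus \code{drop}
#' percentage points (on the same scale as \code{smoothed}). The remap time
#' is the number of episodes from the reversal until the smoothed accuracy
#' first re-reaches the criterion after having fallen below it; 0 if it
#' never falls below, \code{NA} (with \code{recovered = FALSE}) if it never
#' recovers.
#'
#' @param smoothed smoothed per-episode accuracy series.
#' @param reversal_episode 1-based episode at which the new mapping begins.
#' @param criterion explicit criterion level; default \code{NULL} uses the
#'   rule above.
#' @param pre_window,drop criterion rule parameters.
#' @return list with \code{episodes}, \code{criterion}, \code{recovered}.
#' @export
remap_time <- function(smoothed, reversal_episode, criterion = NULL,
                       pre_window = 100L, drop = 5) {
  stopifnot(reversal_episode >= 2L, reversal_episode <= length(smoothed))
  if (is.null(criterion)) {
    lo <- max(1L, reversal_episode - pre_window)
    criterion <- mean(smoothed[lo:(reversal_episode - 1L)]) - drop
  }
  post <- smoothed[reversal_episode:length(smoothed)]
  below <- which(post < criterion)
  if (!length(below))
    return(list(episodes = 0L, criterion = criterion, recovered = TRUE))
  rec <- which(post >= criterion & seq_along(post) > below[[1L]])
  if (!length(rec))
    return(list(episodes = NA_integer_, criterion = criterion,
                recovered = FALSE))
  list(episodes = rec[[1L]] - 1L, criterion = criterion, recovered = TRUE)
}

#' D2/D1 population activity ratio over an episode window
#'
#' @param d1_spikes,d2_spikes per-episode total spike counts.
#' @param window integer vector of episode indices (1-based).
#' @return total D2 spikes / total D1 spikes in the window; \code{NA} when
#'   no D1 spikes occurred.
#' @export
d2_d1_ratio <- function(d1_spikes, d2_spikes, window) {
  stopifnot(all(window >= 1L), all(window <= length(d1_spikes)),
            length(d1_spikes) == length(d2_spikes))
  s1 <- sum(d1_spikes[window])
  if (s1 == 0) return(NA_real_)
  sum(d2_spikes[window]) / s1
}
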