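## Spike-rate characterization: Gaussian-kernel rates, randomization-based
## task-responsiveness classification, normalized population PSTHs, and
## delay-period condition comparisons.

#' Gaussian-kernel spike rate
#'
#' Convolves each trial's spike impulse train with a unit-area Gaussian
#' (sigma = 10 ms by default) on the sample grid of the epoch, yielding a
#' rate in Hz, then averages across trials.
#'
#' @param train a `spike_train`
#' @param t0_ms,stop_ms epoch span of the returned rate, ms
#' @param sigma_ms Gaussian SD, ms
#' @param rate_hz sample grid, Hz
#' @return a `rate_series`: `times_ms`, `rate_hz` (trials x time, Hz),
#'   `mean_rate` (trial average), `kernel_sigma_ms`
#' @export
kernel_rate <- function(train, t0_ms = -500, stop_ms = 500, sigma_ms = 10,
                        rate_hz = 1000) {
  stopifnot(sigma_ms > 0)
  dt <- 1000 / rate_hz
  times <- seq(t0_ms, stop_ms - dt, by = dt)
  half <- ceiling(4 * sigma_ms / dt)
  kt <- (-half:half) * dt
  k <- exp(-kt^2 / (2 * sigma_ms^2))
  k <- k / (sum(k) * dt / 1000)           # unit area in seconds -> Hz
  n <- length(train$spike_times_ms)
  rates <- matrix(0, n, length(times))
  for (i in seq_len(n)) {
    st <- train$spike_times_ms[[i]]
    st <- st[st >= t0_ms - 4 * sigma_ms & st < stop_ms + 4 * sigma_ms]
    if (!length(st)) next
    counts <- numeric(length(times) + 2 * half)
    idx <- round((st - (t0_ms - half * dt)) / dt) + 1
    idx <- idx[idx >= 1 & idx <= length(counts)]
    for (ix in idx) counts[ix] <- counts[ix] + 1
    conv <- stats::filter(counts, k, sides = 2)
    rates[i, ] <- conv[half + seq_along(times)]
  }
  rates[is.na(rates)] <- 0
  structure(list(times_ms = times, rate_hz = rates,
                 mean_rate = colMeans(rates), kernel_sigma_ms = sigma_ms,
                 trial_ids = train$trial_ids, unit_id = train$unit_id),
            class = "rate_series")
}

## Trial-averaged mean of a rate series over a half-open window.
window_mean_rate <- function(rs, window, per_trial = FALSE) {
  sel <- rs$times_ms >= window[1] & rs$times_ms < window[2]
  if (per_trial) rowMeans(rs$rate_hz[, sel, drop = FALSE])
  else mean(rs$mean_rate[sel])
}

#' Randomization test of task responsiveness
#'
#' The observed statistic samples, for each trial, the kernel-rate value
#' at one uniformly random time inside the 250 ms response window after
#' the event (cue and/or target) and averages across trials.  The null
#' does the same from the pre-cue baseline (-350 to 0 ms), repeated
#' `n_perm` times; under a homogeneous null the two are exchangeable, so
#' the test is calibrated.  (`response_stat = "mean"` instead compares the
#' window-mean response against the sampled baseline, which is
#' conservative because a window mean has lower variance than a sampled
#' point.)  Increases and decreases are tested as two one-sided tests at
#' alpha/2 each, Holm-corrected across events, and the unit is classed
#' `visual` (cue response), `movement` (target response),
#' `visual_movement`, `decreased`, or `none`.
#'
#' @param cue_rate `rate_series` aligned to the cue, covering [-350, 250)
#' @param target_rate optional `rate_series` aligned to the target,
#'   covering [0, 250); baseline still comes from the pre-cue epoch
#' @param n_perm permutations (5000 by default)
#' @param response_window,baseline_window ms windows
#' @param response_stat `"sampled"` (default, exchangeable with the null)
#'   or `"mean"` (window mean)
#' @param alpha family-wise level
#' @param seed integer seed
#' @return a `responsiveness_result` with per-event one-sided p-values,
#'   directions, and the class label
#' @export
responsiveness_test <- function(cue_rate, target_rate = NULL, n_perm = 5000,
                                response_window = c(0, 250),
                                baseline_window = c(-350, 0),
                                response_stat = c("sampled", "mean"),
                                alpha = 0.05, seed = 1L) {
  response_stat <- match.arg(response_stat)
  n_tr <- nrow(cue_rate$rate_hz)
  if (n_tr < 10) stop2("fewer than 10 trials; refusing to classify")
  set.seed(seed)
  bsel <- which(cue_rate$times_ms >= baseline_window[1] &
                  cue_rate$times_ms < baseline_window[2])
  base_mat <- cue_rate$rate_hz[, bsel, drop = FALSE]
  draw_idx <- matrix(sample.int(length(bsel), n_perm * n_tr, replace = TRUE),
                     n_perm, n_tr)
  null_means <- vapply(seq_len(n_perm), function(r) {
    mean(base_mat[cbind(seq_len(n_tr), draw_idx[r, ])])
  }, numeric(1))

  one_event <- function(rs) {
    obs <- if (response_stat == "mean") {
      window_mean_rate(rs, response_window)
    } else {
      rsel <- which(rs$times_ms >= response_window[1] &
                      rs$times_ms < response_window[2])
      mean(rs$rate_hz[cbind(seq_len(n_tr),
                            rsel[sample.int(length(rsel), n_tr,
                                            replace = TRUE)])])
    }
    p_inc <- (1 + sum(null_means >= obs)) / (n_perm + 1)
    p_dec <- (1 + sum(null_means <= obs)) / (n_perm + 1)
    list(obs = obs, p_inc = p_inc, p_dec = p_dec)
  }
  cue <- one_event(cue_rate)
  events <- list(cue = cue)
  if (!is.null(target_rate)) events$target <- one_event(target_rate)

  # two one-sided tests at alpha/2 each; Holm runs across events within
  # each direction
  p_inc <- vapply(events, `[[`, numeric(1), "p_inc")
  p_dec <- vapply(events, `[[`, numeric(1), "p_dec")
  inc_rej <- holm_correct(p_inc, alpha / 2)
  dec_rej <- holm_correct(p_dec, alpha / 2)
  dirs <- ifelse(inc_rej, "increased", ifelse(dec_rej, "decreased", "none"))
  names(dirs) <- names(events)
  cls <- if (any(dirs == "decreased") && !any(dirs == "increased")) {
    "decreased"
  } else if (identical(unname(dirs["cue"]), "increased") &&
             identical(unname(dirs["target"]), "increased")) {
    "visual_movement"
  } else if (identical(unname(dirs["cue"]), "increased")) {
    "visual"
  } else if (identical(unname(dirs["target"]), "increased")) {
    "movement"
  } else "none"
  structure(list(unit_id = cue_rate$unit_id,
                 cue_p = c(increase = cue$p_inc, decrease = cue$p_dec),
                 target_p = if (!is.null(target_rate))
                   c(increase = events$target$p_inc,
                     decrease = events$target$p_dec) else NULL,
                 direction = dirs, class = cls, n_perm = n_perm),
            class = "responsiveness_result")
}

#' Max-normalized population PSTH
#'
#' Each unit's trial-averaged rate is divided by its own maximum over the
#' epoch, then units are grand-averaged; all values lie in [0, 1].
#' All-zero units are excluded with a warning.
#'
#' @param rates list of `rate_series` on a common time grid
#' @return a `rate_series` holding the normalized population average
#' @export
population_psth <- function(rates) {
  stopifnot(length(rates) >= 1)
  keep <- vapply(rates, function(r) max(r$mean_rate) > 0, logical(1))
  if (!all(keep)) warning(sum(!keep), " all-zero unit(s) excluded")
  rates <- rates[keep]
  if (!length(rates)) stop2("no units with non-zero rates")
  norm <- vapply(rates, function(r) r$mean_rate / max(r$mean_rate),
                 numeric(length(rates[[1]]$mean_rate)))
  structure(list(times_ms = rates[[1]]$times_ms,
                 mean_rate = rowMeans(as.matrix(norm)),
                 n_units = length(rates)), class = "rate_series")
}

#' Delay-period condition comparison (Wilcoxon rank-sum)
#'
#' Compares window-averaged per-trial rates between two attention
#' conditions (receptive field at the cued vs non-cued location) over the
#' pre-target window (500 ms before target by default).
#'
#' @param ratesA,ratesB `rate_series` for the two conditions
#' @param window averaging window, ms
#' @return the `htest` from [stats::wilcox.test()] (two-sided)
#' @export
delay_comparison <- function(ratesA, ratesB, window = c(-500, 0)) {
  a <- window_mean_rate(ratesA, window, per_trial = TRUE)
  b <- window_mean_rate(ratesB, window, per_trial = TRUE)
  if (!length(a) || !length(b)) stop2("empty sample")
  stats::wilcox.test(a, b, alternative = "two.sided", exact = NULL)
}
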