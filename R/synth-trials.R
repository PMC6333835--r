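## Task-structure generator: trial tables with the spatial-cueing design
## (two bar objects, 78% cue validity, 10% catch, 12% non-cued targets) and
## Bernoulli outcomes whose hit probability follows pre-target theta phase.

#' Task configuration for the synthetic trial generator
#'
#' Defaults encode the study design: 78% cue validity, 10% catch trials,
#' 12% non-cued targets (split equally between the same-object and
#' different-object locations), fixation and bar-cue delays uniform in
#' 500-1200 ms, cue-target delay uniform in 300-1600 ms.
#'
#' @param n_trials number of trials
#' @param p_valid probability the target appears at the cued location
#' @param p_catch probability of a catch trial (no target)
#' @param p_noncued probability of a target at a non-cued location
#' @param fixation_delay_range,bar_cue_delay_range,cue_target_delay_range
#'   uniform delay ranges, ms
#' @param seed integer seed
#' @return a `task_config` list
#' @export
task_config <- function(n_trials = 1000, p_valid = 0.78, p_catch = 0.10,
                        p_noncued = 0.12,
                        fixation_delay_range = c(500, 1200),
                        bar_cue_delay_range = c(500, 1200),
                        cue_target_delay_range = c(300, 1600),
                        seed = 1L) {
  if (abs(p_valid + p_catch + p_noncued - 1) > 1e-12)
    stop2("p_valid + p_catch + p_noncued must sum to 1")
  structure(list(n_trials = n_trials, p_valid = p_valid, p_catch = p_catch,
                 p_noncued = p_noncued,
                 fixation_delay_range = fixation_delay_range,
                 bar_cue_delay_range = bar_cue_delay_range,
                 cue_target_delay_range = cue_target_delay_range,
                 seed = seed), class = "task_config")
}

## Quadrants 1..4 = UL, UR, LL, LR.  Horizontal bars pair {1,2} and {3,4};
## vertical bars pair {1,3} and {2,4}.  The same-object location is the
## other end of the cued bar; the different-object location is the mirrored
## end of the second bar.
same_object_quadrant <- function(q, orientation) {
  h <- c(2L, 1L, 4L, 3L)  # horizontal partner
  v <- c(3L, 4L, 1L, 2L)  # vertical partner
  ifelse(orientation == "horizontal", h[q], v[q])
}
different_object_quadrant <- function(q, orientation) {
  h <- c(3L, 4L, 1L, 2L)
  v <- c(2L, 1L, 4L, 3L)
  ifelse(orientation == "horizontal", h[q], v[q])
}

#' Generate a synthetic trial table
#'
#' Draws per-trial delays uniformly in the configured ranges and assigns the
#' target location by the cue-validity/catch/non-cued probabilities.
#' Outcomes are placeholders (`miss` / `catch_correct`) until
#' [synthesize_behavior()] assigns phase-dependent ones.
#'
#' @param config a [task_config()]
#' @return a `trial_table`
#' @export
generate_trials <- function(config) {
  stopifnot(inherits(config, "task_config"))
  set.seed(config$seed)
  n <- config$n_trials
  orientation <- sample(c("horizontal", "vertical"), n, replace = TRUE)
  cue_q <- sample.int(4L, n, replace = TRUE)
  kind <- sample(c("cued", "catch", "noncued"), n, replace = TRUE,
                 prob = c(config$p_valid, config$p_catch, config$p_noncued))
  condition <- character(n)
  target_q <- integer(n)
  condition[kind == "cued"] <- "cued"
  target_q[kind == "cued"] <- cue_q[kind == "cued"]
  condition[kind == "catch"] <- "catch"
  target_q[kind == "catch"] <- NA_integer_
  nc <- which(kind == "noncued")
  same <- nc[stats::runif(length(nc)) < 0.5]
  diff_ <- setdiff(nc, same)
  condition[same] <- "same_object"
  target_q[same] <- same_object_quadrant(cue_q[same], orientation[same])
  condition[diff_] <- "different_object"
  target_q[diff_] <- different_object_quadrant(cue_q[diff_], orientation[diff_])
  runifr <- function(r) stats::runif(n, r[1], r[2])
  trial_table(data.frame(
    trial_id = seq_len(n),
    bar_orientation = orientation,
    cue_quadrant = cue_q,
    target_quadrant = target_q,
    condition = condition,
    fixation_delay_ms = runifr(config$fixation_delay_range),
    bar_cue_delay_ms = runifr(config$bar_cue_delay_range),
    cue_target_delay_ms = runifr(config$cue_target_delay_range),
    outcome = ifelse(condition == "catch", "catch_correct", "miss"),
    response_time_ms = NA_real_,
    stringsAsFactors = FALSE
  ))
}

#' Behavioral outcome configuration
#'
#' Hit probability on target trials is a one-cycle sinusoid of the
#' pre-target theta phase: `P(hit) = p0 + m * cos(phase - good_phase)`.
#' An optional nested modulation multiplies in only while theta phase lies
#' within the chosen half-cycle, emulating theta-gated higher-frequency
#' behavioral rhythms.
#'
#' @param p0 base hit rate
#' @param theta_mod_depth modulation depth `m` (probability units)
#' @param good_phase_deg theta phase of best detection, degrees
#' @param estimation_time_ms when pre-target phase is evaluated (default -250)
#' @param nested optional list: `depth`, `active_bin` ("good" or "poor") and
#'   `good_phase_deg` for the nested (alpha/low-beta carrier) phase
#' @param seed integer seed
#' @export
behavior_config <- function(p0 = 0.5, theta_mod_depth = 0.2,
                            good_phase_deg = 90, estimation_time_ms = -250,
                            nested = NULL, seed = 1L) {
  top <- p0 + theta_mod_depth
  bot <- p0 - theta_mod_depth
  if (!is.null(nested)) {
    top <- top * (1 + nested$depth)
    bot <- bot * (1 - nested$depth)
  }
  if (top > 1 + 1e-12 || bot < -1e-12)
    stop2("hit probability outside [0, 1] for some phase")
  structure(list(p0 = p0, theta_mod_depth = theta_mod_depth,
                 good_phase_deg = good_phase_deg,
                 estimation_time_ms = estimation_time_ms,
                 nested = nested, seed = seed), class = "behavior_config")
}

#' Assign phase-dependent outcomes to target trials
#'
#' Evaluates the generator's analytic theta phase (carried in the LFP's
#' ground-truth metadata) at the pre-target estimation time and draws
#' hit/miss outcomes independently per trial.  Catch trials keep
#' `catch_correct`; aborted trials are untouched.
#'
#' @param trials a `trial_table`
#' @param lfp an `epoched_signal` from [synthesize_lfp()] (provides truth)
#' @param config a [behavior_config()]
#' @return the trial table with outcomes and hit response times filled in
#' @export
synthesize_behavior <- function(trials, lfp, config) {
  stopifnot(inherits(config, "behavior_config"))
  truth <- lfp$truth
  if (is.null(truth)) stop2("lfp carries no generator ground truth")
  set.seed(config$seed)
  t_est <- config$estimation_time_ms
  idx <- match(trials$trial_id, lfp$trial_ids)
  phi_theta <- wrap_pi(2 * pi * truth$theta_freq * t_est / 1000 +
                         truth$theta_phase0[idx])
  p <- config$p0 + config$theta_mod_depth *
    cos(phi_theta - deg2rad(config$good_phase_deg))
  if (!is.null(config$nested)) {
    nst <- config$nested
    gate_center <- deg2rad(config$good_phase_deg) +
      if (identical(nst$active_bin, "poor")) pi else 0
    active <- abs(wrap_pi(phi_theta - gate_center)) <= pi / 2
    phi_n <- wrap_pi(2 * pi * truth$carrier_freq[idx] * t_est / 1000 +
                       truth$carrier_phase0[idx])
    p <- p * ifelse(active,
                    1 + nst$depth * cos(phi_n - deg2rad(nst$good_phase_deg)),
                    1)
  }
  if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE))
    stop2("hit probability outside [0, 1] on some trial")
  p <- pmin(pmax(p, 0), 1)
  tgt <- trials$condition != "catch" & trials$outcome != "aborted"
  hit <- tgt & stats::runif(nrow(trials)) < p
  trials$outcome[tgt] <- ifelse(hit[tgt], "hit", "miss")
  trials$response_time_ms <- NA_real_
  trials$response_time_ms[hit] <- stats::runif(sum(hit), 150, 650)
  trial_table(trials)
}
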