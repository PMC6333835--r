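## End-to-end orchestration: simulate a session with the full generative
## structure, and run the analysis sequence (spiking -> power ->
## phase-detection -> theta bins -> PPC -> Granger -> PAC) with per-stage
## error isolation.

#' Simulate a complete synthetic session
#'
#' Convenience wrapper around the generators: trial table, one LFP per
#' region, phase-coupled spike trains, and phase-dependent behavioral
#' outcomes.  All ground truth is recorded in `meta$truth`.
#'
#' @param task a [task_config()]
#' @param signals named list of [signal_config()] (one per region)
#' @param behavior a [behavior_config()] or NULL (keeps placeholder
#'   outcomes); behavior is driven by the first region's theta
#' @param units named list: each entry a list with `roi`,
#'   `coupling` ([coupling_config()]) and `mean_rate_hz`
#' @param epoch_ms epoch span `(t0, stop)` around the target
#' @param seed integer master seed (overrides the config seeds)
#' @return an `rn_session`
#' @export
simulate_session <- function(task = task_config(),
                             signals = list(region1 = signal_config()),
                             behavior = behavior_config(),
                             units = list(),
                             epoch_ms = c(-1000, 250), seed = 1L) {
  seeds <- derive_seeds(seed, 3 + length(signals) + length(units))
  task$seed <- seeds[1]
  trials <- generate_trials(task)
  lfps <- list()
  for (i in seq_along(signals)) {
    cfg <- signals[[i]]
    cfg$seed <- seeds[2 + i]
    lfps[[names(signals)[i]]] <-
      synthesize_lfp(trials, cfg, t0_ms = epoch_ms[1], stop_ms = epoch_ms[2],
                     roi = names(signals)[i])
  }
  if (!is.null(behavior)) {
    behavior$seed <- seeds[2]
    trials <- synthesize_behavior(trials, lfps[[1]], behavior)
  }
  sts <- list()
  for (i in seq_along(units)) {
    u <- units[[i]]
    cc <- u$coupling
    cc$seed <- seeds[2 + length(signals) + i]
    sts[[names(units)[i]]] <-
      synthesize_spikes(lfps[[u$roi]], cc, mean_rate_hz = u$mean_rate_hz,
                        unit_id = names(units)[i], roi = u$roi)
  }
  truth <- list(task = unclass(task),
                behavior = if (!is.null(behavior)) unclass(behavior),
                signals = lapply(signals, unclass))
  session(trials, lfps, sts, meta = list(truth = truth, seed = seed))
}

#' Default analysis configuration
#'
#' One declarative list mirroring every module's knobs; unknown keys are
#' rejected by [run_pipeline()].
#'
#' @param ... overrides of the defaults
#' @export
analysis_config <- function(...) {
  cfg <- list(
    detection_freqs = seq(3, 60, by = 1),
    theta_binned_freqs = seq(9, 60, by = 1),
    estimation_time_ms = -250,
    wavelet_cycles = 3,
    theta_wavelet_cycles = 2,
    n_perm = 1500,
    power_window = c(-500, 0),
    spike_window = c(-500, -125),
    response_window = c(0, 250),
    baseline_window = c(-350, 0),
    min_trials = 50,
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop2("unknown config keys: ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, dots)
}

run_stage <- function(report, name, expr) {
  report[[name]] <- tryCatch(
    list(ok = TRUE, result = force(expr)),
    error = function(e) list(ok = FALSE, reason = conditionMessage(e)))
  report
}

#' Run the full analysis pipeline on a session
#'
#' Executes the stages in dependency order; a failing or refusing stage is
#' recorded with its reason and its dependents are skipped.
#'
#' @param s an `rn_session`
#' @param config an [analysis_config()]
#' @return a `report` list: per-stage `ok`/`result` or `reason`, plus
#'   provenance (`config`, `seed`)
#' @export
run_pipeline <- function(s, config = analysis_config()) {
  validate_session(s)
  rep <- list()
  keep <- analyzable_trials(s$trials)
  lfp <- s$lfps[[1]]
  rows <- lfp$trial_ids %in% s$trials$trial_id[keep]
  lfp_keep <- lfp
  lfp_keep$samples <- lfp$samples[rows, , drop = FALSE]
  lfp_keep$trial_ids <- lfp$trial_ids[rows]

  rep <- run_stage(rep, "power", {
    irasa(lfp_keep, config$power_window)
  })

  if (length(s$units)) {
    rep <- run_stage(rep, "spikes", {
      lapply(s$units, function(u) {
        kr <- kernel_rate(u, t0_ms = config$baseline_window[1],
                          stop_ms = config$response_window[2])
        responsiveness_test(kr, n_perm = 5000,
                            response_window = config$response_window,
                            baseline_window = config$baseline_window,
                            seed = config$seed)
      })
    })
  } else {
    rep$spikes <- list(ok = FALSE, reason = "no spike trains in session")
  }

  rep <- run_stage(rep, "phase_detection", {
    spect <- morlet_transform(lfp_keep, config$detection_freqs,
                              n_cycles = config$wavelet_cycles)
    ph <- pretarget_phase(spect, config$estimation_time_ms)
    outcomes <- s$trials$outcome[keep]
    phase_detection_spectrum(ph, outcomes, config$detection_freqs,
                             n_perm = config$n_perm, seed = config$seed,
                             min_trials = config$min_trials)
  })

  if (isTRUE(rep$phase_detection$ok)) {
    rep <- run_stage(rep, "theta_bins", {
      pd <- rep$phase_detection$result
      i5 <- which.min(abs(pd$freqs_hz - 5))
      define_theta_bins(structure(
        list(mean_level = pd$mean_level[i5], amplitude = pd$amplitude[i5],
             preferred_phase_deg = pd$preferred_phase_deg[i5]),
        class = "sine_fit"),
        estimation_time_ms = config$estimation_time_ms,
        wavelet_cycles = config$theta_wavelet_cycles)
    })
  } else {
    rep$theta_bins <- list(ok = FALSE,
                           reason = "skipped: phase_detection failed")
  }

  if (isTRUE(rep$theta_bins$ok)) {
    rep <- run_stage(rep, "theta_binned_detection", {
      bins <- rep$theta_bins$result
      th_spect <- morlet_transform(lfp_keep, 5,
                                   n_cycles = config$theta_wavelet_cycles,
                                   times_ms = bins$estimation_time_ms)
      theta_phase <- drop(Arg(th_spect$coef[[1]]))
      hf_spect <- morlet_transform(lfp_keep, config$theta_binned_freqs,
                                   n_cycles = config$wavelet_cycles)
      ph <- pretarget_phase(hf_spect, config$estimation_time_ms)
      theta_binned_phase_detection(ph, s$trials$outcome[keep], theta_phase,
                                   bins, config$theta_binned_freqs,
                                   n_perm = config$n_perm,
                                   seed = config$seed,
                                   min_trials = config$min_trials)
    })
  } else {
    rep$theta_binned_detection <- list(ok = FALSE,
                                       reason = "skipped: no theta bins")
  }

  if (length(s$units)) {
    rep <- run_stage(rep, "ppc", {
      spect <- morlet_transform(lfp_keep, config$theta_binned_freqs,
                                n_cycles = config$wavelet_cycles)
      lapply(s$units, function(u) {
        sp <- extract_spike_phases(u, spect, window = config$spike_window)
        ppc_spectrum(sp)
      })
    })
  } else {
    rep$ppc <- list(ok = FALSE, reason = "no spike trains in session")
  }

  if (length(s$lfps) >= 2) {
    rep <- run_stage(rep, "granger", {
      ep <- preprocess_gc(s$lfps[1:2])
      ep$data <- ep$data[rows, , , drop = FALSE]
      m <- fit_mvar(ep, order = 8)
      spectral_granger(m)
    })
  } else {
    rep$granger <- list(ok = FALSE, reason = "fewer than two LFP channels")
  }

  rep <- run_stage(rep, "pac", {
    times <- seq(-750, -200, by = 10)
    th <- morlet_transform(lfp_keep, 5, n_cycles = config$wavelet_cycles,
                           times_ms = times)
    pw_freqs <- seq(9, 60, by = 3)
    pw <- morlet_transform(lfp_keep, pw_freqs,
                           n_cycles = config$wavelet_cycles,
                           times_ms = times)
    within_region_pac(Arg(th$coef[[1]]),
                      lapply(pw$coef, function(m) Mod(m)^2),
                      pw_freqs, n_perm = config$n_perm, seed = config$seed)
  })

  structure(list(stages = rep, config = config, seed = config$seed,
                 package_version = as.character(
                   utils::packageVersion("rhythmnet"))),
            class = "rn_report")
}
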