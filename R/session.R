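## Session containers: trial table, epoched LFPs, spike trains.
##
## Time convention everywhere: milliseconds, alignment event at t = 0,
## half-open analysis windows [start, stop).

TRIAL_CONDITIONS <- c("cued", "same_object", "different_object", "catch")
TRIAL_OUTCOMES <- c("hit", "miss", "false_alarm", "catch_correct", "aborted")

#' Construct a trial table
#'
#' One row per trial of the spatial-cueing (Egly-Driver) task: two bar-shaped
#' objects, a peripheral cue at one bar end, and a low-contrast target at the
#' cued location (valid trials), a non-cued location on the same or the other
#' object, or no target at all (catch trials).
#'
#' @param df data.frame with columns `trial_id`, `bar_orientation`,
#'   `cue_quadrant`, `target_quadrant` (NA for catch), `condition`,
#'   `fixation_delay_ms`, `bar_cue_delay_ms`, `cue_target_delay_ms`,
#'   `outcome`, `response_time_ms` (NA when no response).
#' @return validated `trial_table` (a data.frame subclass)
#' @export
trial_table <- function(df) {
  req <- c("trial_id", "bar_orientation", "cue_quadrant", "target_quadrant",
           "condition", "fixation_delay_ms", "bar_cue_delay_ms",
           "cue_target_delay_ms", "outcome", "response_time_ms")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop2("trial table missing columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[req]
  if (anyDuplicated(df$trial_id))
    stop2("duplicated trial_id values")
  if (!all(df$condition %in% TRIAL_CONDITIONS))
    stop2("unknown condition labels")
  if (!all(df$outcome %in% TRIAL_OUTCOMES))
    stop2("unknown outcome labels")
  is_catch <- df$condition == "catch"
  if (!all(is.na(df$target_quadrant[is_catch])) ||
      any(is.na(df$target_quadrant[!is_catch])))
    stop2("catch trials and only catch trials must have no target quadrant")
  ctd <- df$cue_target_delay_ms
  if (any(ctd < 300 | ctd > 1600))
    stop2("cue_target_delay_ms outside [300, 1600]")
  oth <- c(df$fixation_delay_ms, df$bar_cue_delay_ms)
  if (any(oth < 500 | oth > 1200))
    stop2("fixation/bar-cue delays outside [500, 1200]")
  hits <- df$outcome == "hit"
  rt <- df$response_time_ms[hits]
  if (any(is.na(rt)) || any(rt < 150 | rt > 650))
    stop2("hit trials require response_time_ms in [150, 650]")
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Construct an epoched LFP signal
#'
#' @param samples numeric matrix, trials x time, microvolts
#' @param rate_hz sampling rate (1000 native)
#' @param t0_ms time of the first sample relative to the alignment event
#' @param trial_ids integer ids matching the session trial table
#' @param roi,channel labels
#' @param alignment_event `"cue"` or `"target"`
#' @return `epoched_signal` object
#' @export
epoched_signal <- function(samples, rate_hz, t0_ms, trial_ids,
                           roi = "roi", channel = "ch1",
                           alignment_event = c("cue", "target")) {
  alignment_event <- match.arg(alignment_event)
  samples <- as.matrix(samples)
  stopifnot(rate_hz > 0, nrow(samples) == length(trial_ids))
  if (!all(is.finite(samples))) stop2("non-finite LFP samples")
  structure(list(
    roi = roi, channel = channel, alignment_event = alignment_event,
    t0_ms = t0_ms, rate_hz = rate_hz, samples = samples,
    trial_ids = as.integer(trial_ids)
  ), class = "epoched_signal")
}

#' Sample times of an epoched signal (ms, relative to alignment event)
#' @param x an `epoched_signal`
#' @return numeric vector, one value per column of `x$samples`
#' @export
signal_times <- function(x) {
  x$t0_ms + (seq_len(ncol(x$samples)) - 1L) * 1000 / x$rate_hz
}

#' Construct a spike train
#'
#' @param spike_times_ms list (one element per trial) of sorted spike times
#'   in ms relative to the alignment event
#' @param trial_ids matching trial ids
#' @param unit_id,roi labels
#' @param alignment_event `"cue"` or `"target"`
#' @export
spike_train <- function(spike_times_ms, trial_ids, unit_id = "u1",
                        roi = "roi", alignment_event = c("cue", "target")) {
  alignment_event <- match.arg(alignment_event)
  stopifnot(length(spike_times_ms) == length(trial_ids))
  ok <- vapply(spike_times_ms, function(t) !is.unsorted(t), logical(1))
  if (!all(ok)) stop2("spike times must be sorted within trial")
  structure(list(
    unit_id = unit_id, roi = roi, alignment_event = alignment_event,
    spike_times_ms = lapply(spike_times_ms, as.numeric),
    trial_ids = as.integer(trial_ids)
  ), class = "spike_train")
}

#' Assemble a recording session
#'
#' @param trials a `trial_table`
#' @param lfps named list of `epoched_signal`
#' @param units named list of `spike_train`
#' @param meta free-form provenance list (animal, date, receptive-field
#'   quadrant per region, generator ground truth, ...)
#' @export
session <- function(trials, lfps = list(), units = list(), meta = list()) {
  s <- structure(list(trials = trials, lfps = lfps, units = units,
                      meta = meta), class = "rn_session")
  validate_session(s)
  s
}

#' Validate cross-references within a session
#'
#' Checks every LFP and spike-train trial id against the trial table and the
#' internal invariants of each container.
#'
#' @param s an `rn_session`
#' @return `s`, invisibly; signals an error describing the first violation
#' @export
validate_session <- function(s) {
  stopifnot(inherits(s, "rn_session"))
  ids <- s$trials$trial_id
  for (nm in names(s$lfps)) {
    bad <- setdiff(s$lfps[[nm]]$trial_ids, ids)
    if (length(bad))
      stop2("lfp '", nm, "' references unknown trial(s): ",
            paste(bad, collapse = ", "))
  }
  for (nm in names(s$units)) {
    bad <- setdiff(s$units[[nm]]$trial_ids, ids)
    if (length(bad))
      stop2("unit '", nm, "' references unknown trial(s): ",
            paste(bad, collapse = ", "))
  }
  invisible(s)
}

#' Trials eligible for analysis
#'
#' Aborted trials are kept in the session but excluded from every analysis;
#' catch trials are additionally excluded where target-locked quantities are
#' needed.
#'
#' @param trials a `trial_table`
#' @param drop_catch also drop catch trials (default TRUE)
#' @return logical vector over rows of `trials`
#' @export
analyzable_trials <- function(trials, drop_catch = TRUE) {
  keep <- trials$outcome != "aborted"
  if (drop_catch) keep <- keep & trials$condition != "catch"
  keep
}

#' Extract a sub-window of an epoched signal
#'
#' Half-open convention: the returned epoch covers `[start_ms, stop_ms)`,
#' so adjacent windows concatenate without duplication.
#'
#' @param signal an `epoched_signal`
#' @param start_ms,stop_ms window bounds in ms relative to alignment
#' @return an `epoched_signal` covering the window
#' @export
epoch_window <- function(signal, start_ms, stop_ms) {
  stopifnot(inherits(signal, "epoched_signal"), start_ms < stop_ms)
  dt <- 1000 / signal$rate_hz
  n <- ncol(signal$samples)
  i0 <- round((start_ms - signal$t0_ms) / dt)
  n_out <- round((stop_ms - start_ms) * signal$rate_hz / 1000)
  if (i0 < 0 || i0 + n_out > n)
    stop2("window [", start_ms, ", ", stop_ms, ") outside epoch span [",
          signal$t0_ms, ", ", signal$t0_ms + n * dt, ")")
  out <- signal
  out$samples <- signal$samples[, i0 + seq_len(n_out), drop = FALSE]
  out$t0_ms <- signal$t0_ms + i0 * dt
  out
}

## ---------------------------------------------------------------------------
## On-disk layout (plain text): <dir>/trials.csv, <dir>/lfp/<roi>__<channel>.csv
## (one trial per row, first columns carry the header metadata via a JSON
## sidecar), <dir>/spikes/<unit>.json, <dir>/meta.json.

#' Write a session to a directory
#'
#' Plain-text layout: `trials.csv` for the trial table, one CSV per LFP
#' channel under `lfp/` with a JSON sidecar of its metadata, one JSON file
#' per unit under `spikes/`, and `meta.json`.
#'
#' @param s an `rn_session`
#' @param path directory to create/fill
#' @return `path`, invisibly
#' @export
save_session <- function(s, path) {
  validate_session(s)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(s$trials), file.path(path, "trials.csv"),
                   row.names = FALSE)
  dir.create(file.path(path, "lfp"), showWarnings = FALSE)
  dir.create(file.path(path, "spikes"), showWarnings = FALSE)
  for (nm in names(s$lfps)) {
    x <- s$lfps[[nm]]
    base <- file.path(path, "lfp", nm)
    utils::write.csv(as.data.frame(x$samples), paste0(base, ".csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(roi = x$roi, channel = x$channel,
           alignment_event = x$alignment_event, t0_ms = x$t0_ms,
           rate_hz = x$rate_hz, trial_ids = x$trial_ids),
      paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  }
  for (nm in names(s$units)) {
    x <- s$units[[nm]]
    jsonlite::write_json(
      list(unit_id = x$unit_id, roi = x$roi,
           alignment_event = x$alignment_event, trial_ids = x$trial_ids,
           spike_times_ms = x$spike_times_ms),
      file.path(path, "spikes", paste0(nm, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(s$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a session from a directory
#'
#' Inverse of [save_session()]; validates all cross-references on load.
#'
#' @param path session directory
#' @return an `rn_session`
#' @export
load_session <- function(path) {
  tf <- file.path(path, "trials.csv")
  if (!file.exists(tf)) stop2("missing trial table file: ", tf)
  tr <- utils::read.csv(tf, stringsAsFactors = FALSE)
  if ("response_time_ms" %in% names(tr))
    tr$response_time_ms <- as.numeric(tr$response_time_ms)
  if ("target_quadrant" %in% names(tr))
    tr$target_quadrant <- as.integer(tr$target_quadrant)
  if (nrow(tr)) {
    trials <- trial_table(tr)
  } else {
    class(tr) <- c("trial_table", "data.frame")
    trials <- tr
  }
  lfps <- list()
  for (f in sort(list.files(file.path(path, "lfp"), pattern = "\\.csv$",
                            full.names = TRUE))) {
    nm <- sub("\\.csv$", "", basename(f))
    hdr <- jsonlite::read_json(sub("\\.csv$", ".json", f), simplifyVector = TRUE)
    samples <- as.matrix(utils::read.csv(f))
    dimnames(samples) <- NULL
    lfps[[nm]] <- epoched_signal(samples, hdr$rate_hz, hdr$t0_ms,
                                 hdr$trial_ids, hdr$roi, hdr$channel,
                                 hdr$alignment_event)
  }
  units <- list()
  for (f in sort(list.files(file.path(path, "spikes"), pattern = "\\.json$",
                            full.names = TRUE))) {
    nm <- sub("\\.json$", "", basename(f))
    u <- jsonlite::read_json(f, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
    st <- u$spike_times_ms
    if (is.null(st)) st <- rep(list(numeric(0)), length(u$trial_ids))
    st <- lapply(st, function(t) if (is.null(t)) numeric(0) else as.numeric(t))
    units[[nm]] <- spike_train(st, u$trial_ids, u$unit_id, u$roi,
                               u$alignment_event)
  }
  meta <- list()
  mf <- file.path(path, "meta.json")
  if (file.exists(mf)) meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  session(trials, lfps, units, meta)
}
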