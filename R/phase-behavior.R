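## Phase-detection analysis: behavioral hit rate as a function of
## pre-target oscillatory phase, summarized per frequency by the amplitude
## of a fitted one-cycle sine (the FFT second component of the 72-bin
## phase function), with outcome-shuffle permutation nulls.

N_PHASE_BINS <- 72L          # centers 0, 5, ..., 355 deg
BIN_HALFWIDTH_DEG <- 90     # each bin pools trials within [-90, +90) deg

#' Phase-bin centers in degrees
#' @export
phase_bin_centers <- function() seq(0, 355, by = 5)

## Fine-bin index in 0..71: phases on [5j, 5(j+1)) land in fine bin j.
## Because the 180-degree boxcar edges align with the 5-degree grid, pooling
## fine bins j = k-18 .. k+17 reproduces the half-open coarse bin
## [center_k - 90, center_k + 90) exactly.
fine_bin <- function(phase_rad) {
  as.integer(floor(wrap_360(rad2deg(phase_rad)) / 5)) %% N_PHASE_BINS
}

## 72 x 72 circulant matrix mapping fine-bin sums to coarse-bin sums.
boxcar_matrix <- function() {
  C <- matrix(0, N_PHASE_BINS, N_PHASE_BINS)
  for (k in seq_len(N_PHASE_BINS)) {
    j <- ((k - 1) + (-18:17)) %% N_PHASE_BINS + 1
    C[k, j] <- 1
  }
  C
}

#' Bin a per-trial quantity by oscillatory phase
#'
#' Values are averaged within 72 overlapping 180-degree phase bins whose
#' centers step by 5 degrees; every trial contributes to exactly 36 bins.
#' Empty bins are flagged `NaN`.
#'
#' @param phases per-trial phases, radians (cosine convention)
#' @param values per-trial quantity (e.g., hit = 1 / miss = 0)
#' @return a `phase_binned_function`: `bin_centers_deg`, `values`,
#'   `n_per_bin`
#' @export
phase_binned_values <- function(phases, values) {
  stopifnot(length(phases) == length(values))
  fb <- fine_bin(phases)
  sums <- counts <- numeric(N_PHASE_BINS)
  agg <- rowsum(cbind(values, 1), fb)
  idx <- as.integer(rownames(agg)) + 1L
  sums[idx] <- agg[, 1]; counts[idx] <- agg[, 2]
  C <- boxcar_matrix()
  S <- drop(C %*% sums); N <- drop(C %*% counts)
  v <- ifelse(N > 0, S / N, NaN)
  structure(list(bin_centers_deg = phase_bin_centers(), values = v,
                 n_per_bin = N, bin_halfwidth_deg = BIN_HALFWIDTH_DEG),
            class = "phase_binned_function")
}

#' Hit rate within overlapping phase bins
#'
#' @param phases per-trial pre-target phases, radians
#' @param outcomes per-trial `"hit"`/`"miss"` labels or logical hits
#' @return a `phase_binned_function` of hit rates
#' @export
phase_binned_hit_rate <- function(phases, outcomes) {
  if (is.character(outcomes)) outcomes <- outcomes == "hit"
  phase_binned_values(phases, as.numeric(outcomes))
}

## Least-squares one-cycle cosine fit for one or many 72-bin functions.
## V: bins x m matrix (NaN rows excluded via mask).  On a complete grid the
## design is orthogonal and the fit equals the 72-point DFT second
## component.  Returns amplitude, preferred phase (deg), mean level.
sine_fit_matrix <- function(V) {
  V <- as.matrix(V)
  mask <- stats::complete.cases(V) & apply(is.finite(V), 1, all)
  if (sum(!mask) > 4) stop2("more than 4 flagged phase bins; refusing to fit")
  th <- deg2rad(phase_bin_centers())[mask]
  X <- cbind(1, cos(th), sin(th))
  coef <- solve(crossprod(X), crossprod(X, V[mask, , drop = FALSE]))
  a <- coef[2, ]; b <- coef[3, ]
  list(mean_level = coef[1, ], amplitude = sqrt(a^2 + b^2),
       preferred_phase_deg = wrap_360(rad2deg(atan2(b, a))))
}

#' One-cycle sine fit of a 72-bin phase function
#'
#' Fits `mean + A * cos(phase - preferred)`; on the complete 72-point grid
#' this equals keeping the second FFT component, whose absolute value is
#' the amplitude of a one-cycle oscillation (the hypothesized shape: a peak
#' separated from a trough by 180 degrees).  Up to 4 flagged bins are
#' excluded from the fit; more refuse.
#'
#' @param f a `phase_binned_function` (or a bare 72-vector)
#' @return a `sine_fit`: `mean_level`, `amplitude` (>= 0),
#'   `preferred_phase_deg` in [0, 360)
#' @export
one_cycle_sine_amplitude <- function(f) {
  v <- if (inherits(f, "phase_binned_function")) f$values else f
  stopifnot(length(v) == N_PHASE_BINS)
  ft <- sine_fit_matrix(matrix(v, ncol = 1))
  structure(list(mean_level = ft$mean_level[[1]],
                 amplitude = ft$amplitude[[1]],
                 preferred_phase_deg = ft$preferred_phase_deg[[1]]),
            class = "sine_fit")
}

#' Per-trial pre-target phase estimates
#'
#' Takes the angle of the complex Morlet output at the estimation time
#' (nearest spectrogram sample), per trial and frequency.
#'
#' @param spect a `complex_spectrogram`
#' @param t_est_ms estimation time (default -250 ms before the target)
#' @return trials x frequency matrix of phases in [-pi, pi)
#' @export
pretarget_phase <- function(spect, t_est_ms = -250) {
  idx <- which.min(abs(spect$times_ms - t_est_ms))
  sapply(seq_along(spect$freqs_hz), function(j) {
    if (!spect$edge_ok[[j]][idx])
      stop2("estimation time ", t_est_ms,
            " ms is edge-contaminated at ", spect$freqs_hz[j], " Hz")
    Arg(spect$coef[[j]][, idx])
  })
}

#' Phase-detection spectrum with outcome-shuffle permutation null
#'
#' For each frequency, bins hit rate by pre-target phase, fits the
#' one-cycle sine, and compares its amplitude against a null built by
#' shuffling behavioral outcomes relative to phases (the same shuffles are
#' applied at every frequency).  P-values use the +1 correction (floor
#' `1/(n_perm+1)`); Holm correction runs across frequencies.
#'
#' @param phases trials x frequency matrix from [pretarget_phase()]
#' @param outcomes per-trial `"hit"`/`"miss"` or logical hits
#' @param freqs frequency labels, Hz
#' @param n_perm permutations (1500 by default)
#' @param seed integer seed
#' @param min_trials refuse below this many analyzable trials
#' @return a `phase_detection_spectrum`: per-frequency `amplitude`,
#'   `preferred_phase_deg`, `mean_level`, `p`, `holm_significant`, plus the
#'   null amplitude matrix
#' @export
phase_detection_spectrum <- function(phases, outcomes, freqs,
                                     n_perm = 1500, seed = 1L,
                                     min_trials = 50) {
  phases <- as.matrix(phases)
  if (is.character(outcomes)) outcomes <- outcomes == "hit"
  y <- as.numeric(outcomes)
  n <- length(y)
  if (n < min_trials) stop2("fewer than ", min_trials, " analyzable trials")
  stopifnot(nrow(phases) == n, ncol(phases) == length(freqs))
  set.seed(seed)
  Y <- cbind(y, replicate(n_perm, y[sample.int(n)]))
  C <- boxcar_matrix()
  amp <- phase_deg <- lvl <- p <- numeric(length(freqs))
  null_amp <- matrix(NA_real_, n_perm, length(freqs))
  for (j in seq_along(freqs)) {
    fb <- fine_bin(phases[, j])
    counts <- numeric(N_PHASE_BINS)
    tab <- table(factor(fb, levels = 0:(N_PHASE_BINS - 1)))
    counts[] <- as.numeric(tab)
    H <- rowsum(Y, fb)
    Hfull <- matrix(0, N_PHASE_BINS, ncol(Y))
    Hfull[as.integer(rownames(H)) + 1L, ] <- H
    N_k <- drop(C %*% counts)
    V <- (C %*% Hfull) / N_k
    V[N_k == 0, ] <- NaN
    ft <- sine_fit_matrix(V)
    amp[j] <- ft$amplitude[1]
    phase_deg[j] <- ft$preferred_phase_deg[1]
    lvl[j] <- ft$mean_level[1]
    null_amp[, j] <- ft$amplitude[-1]
    p[j] <- (1 + sum(null_amp[, j] >= amp[j])) / (n_perm + 1)
  }
  structure(list(freqs_hz = freqs, amplitude = amp,
                 preferred_phase_deg = phase_deg, mean_level = lvl,
                 p = p, holm_significant = holm_correct(p),
                 null_amplitude = null_amp, n_perm = n_perm),
            class = "phase_detection_spectrum")
}

#' Define the good/poor theta-phase bins
#'
#' The "good" theta phase is the peak of the 5 Hz phase-detection sine fit;
#' the "poor" phase lies 180 degrees away.
#'
#' @param fit_at_5hz a `sine_fit` at 5 Hz
#' @param estimation_time_ms where theta phase is read (default -250 ms)
#' @param wavelet_cycles wavelet width used for the binning phase (2)
#' @return a `theta_bin_definition`
#' @export
define_theta_bins <- function(fit_at_5hz, estimation_time_ms = -250,
                              wavelet_cycles = 2) {
  good <- wrap_360(fit_at_5hz$preferred_phase_deg)
  structure(list(freq_hz = 5, good_center_deg = good,
                 poor_center_deg = wrap_360(good + 180),
                 estimation_time_ms = estimation_time_ms,
                 wavelet_cycles = wavelet_cycles),
            class = "theta_bin_definition")
}

#' Assign trials to the good or poor theta half-cycle
#' @param theta_phase per-trial theta phase, radians
#' @param bins a `theta_bin_definition`
#' @return factor with levels `good`, `poor`
#' @export
assign_theta_bin <- function(theta_phase, bins) {
  d <- abs(wrap_pi(theta_phase - deg2rad(bins$good_center_deg)))
  factor(ifelse(d <= pi / 2, "good", "poor"), levels = c("good", "poor"))
}

#' Theta-binned phase-detection re-analysis
#'
#' Splits trials by their pre-target theta phase (2-cycle 5 Hz wavelet at
#' -250 ms) into the good and poor half-cycles and reruns the full
#' phase-detection spectrum at 9-60 Hz separately within each bin, each
#' with its own shuffle null.
#'
#' @param phases trials x frequency matrix (9-60 Hz phases)
#' @param outcomes per-trial outcomes
#' @param theta_phase per-trial theta phase, radians
#' @param bins a `theta_bin_definition`
#' @param freqs frequency labels
#' @param n_perm,seed,min_trials as in [phase_detection_spectrum()]
#' @return list with elements `good` and `poor`
#' @export
theta_binned_phase_detection <- function(phases, outcomes, theta_phase,
                                         bins, freqs, n_perm = 1500,
                                         seed = 1L, min_trials = 50) {
  grp <- assign_theta_bin(theta_phase, bins)
  seeds <- derive_seeds(seed, 2)
  out <- list()
  for (b in c("good", "poor")) {
    sel <- grp == b
    if (sum(sel) < min_trials)
      stop2("theta bin '", b, "' has fewer than ", min_trials, " trials")
    out[[b]] <- phase_detection_spectrum(
      phases[sel, , drop = FALSE],
      if (is.character(outcomes)) outcomes[sel] else outcomes[sel],
      freqs, n_perm = n_perm, seed = seeds[match(b, c("good", "poor"))],
      min_trials = min_trials)
  }
  out
}
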