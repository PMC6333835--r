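## Spike-LFP pairwise phase consistency (PPC): spike-phase extraction,
## the bias-free PPC estimator, attention-condition permutation contrasts,
## theta-phase-dependent PPC, and the power-equating stratification control.

#' Extract LFP phases at spike times
#'
#' For each spike inside the analysis window (-500 to -125 ms before the
#' target by default), reads the LFP phase at the nearest spectrogram
#' sample, per frequency.  Edge-contaminated samples are excluded.
#'
#' @param train a `spike_train`
#' @param spect a `complex_spectrogram` from the paired LFP channel
#' @param window half-open spike-time window, ms
#' @return a `spike_phase_set`: `freqs_hz`, `phases` and `power`
#'   (n_spikes x freq), `trial_index` (row of the spectrogram per spike),
#'   `spike_times_ms`, `n_spikes`; flagged empty when no spikes fall in
#'   the window
#' @export
extract_spike_phases <- function(train, spect, window = c(-500, -125)) {
  stopifnot(inherits(train, "spike_train"),
            inherits(spect, "complex_spectrogram"))
  ok_all <- Reduce(`&`, spect$edge_ok)
  t_ok <- spect$times_ms[ok_all]
  rows <- match(train$trial_ids, spect$trial_ids)
  tr_idx <- integer(0); st <- numeric(0)
  for (i in seq_along(train$spike_times_ms)) {
    s <- train$spike_times_ms[[i]]
    s <- s[s >= window[1] & s < window[2]]
    if (!length(s)) next
    tr_idx <- c(tr_idx, rep(rows[i], length(s)))
    st <- c(st, s)
  }
  if (!length(st)) {
    return(structure(list(freqs_hz = spect$freqs_hz,
                          phases = matrix(NA_real_, 0, length(spect$freqs_hz)),
                          trial_index = integer(0), spike_times_ms = numeric(0),
                          n_spikes = 0L, empty = TRUE),
                     class = "spike_phase_set"))
  }
  col <- vapply(st, function(tt) which.min(abs(t_ok - tt)), 1L)
  col_full <- match(t_ok[col], spect$times_ms)
  cf <- lapply(seq_along(spect$freqs_hz), function(j) {
    spect$coef[[j]][cbind(tr_idx, col_full)]
  })
  ph <- vapply(cf, Arg, numeric(length(st)))
  pw <- vapply(cf, function(z) Mod(z)^2, numeric(length(st)))
  structure(list(freqs_hz = spect$freqs_hz,
                 phases = matrix(ph, ncol = length(spect$freqs_hz)),
                 power = matrix(pw, ncol = length(spect$freqs_hz)),
                 trial_index = tr_idx, spike_times_ms = st,
                 n_spikes = length(st), empty = FALSE),
            class = "spike_phase_set")
}

#' Pairwise phase consistency
#'
#' PPC is the mean cosine of all pairwise phase differences,
#' `2/(n(n-1)) * sum_{i<j} cos(theta_i - theta_j)`, computed through the
#' closed form `(|sum exp(i theta)|^2 - n) / (n(n-1))`.  Unbiased by spike
#' count; expectation `(I1(kappa)/I0(kappa))^2` under von Mises sampling.
#'
#' @param phases radians
#' @return scalar in `[-1/(n-1), 1]`; `NA` when n < 2
#' @export
ppc <- function(phases) {
  n <- length(phases)
  if (n < 2) return(NA_real_)
  (Mod(sum(exp(1i * phases)))^2 - n) / (n * (n - 1))
}

#' PPC spectrum of a spike-phase set
#' @param spikeset a `spike_phase_set`
#' @return a `ppc_spectrum`: `freqs_hz`, `ppc`, `n_spikes`
#' @export
ppc_spectrum <- function(spikeset) {
  structure(list(freqs_hz = spikeset$freqs_hz,
                 ppc = apply(spikeset$phases, 2, ppc),
                 n_spikes = spikeset$n_spikes),
            class = "ppc_spectrum")
}

## Per-trial complex resultants and counts of a spike-phase set:
## S (n_trials_used x freq complex), n (counts).  PPC over any union of
## trials follows from the pooled resultant.
trial_resultants <- function(spikeset) {
  trials <- sort(unique(spikeset$trial_index))
  E <- exp(1i * spikeset$phases)
  grp <- match(spikeset$trial_index, trials)
  S_re <- rowsum(Re(E), grp); S_im <- rowsum(Im(E), grp)
  list(trials = trials, S = S_re + 1i * S_im,
       n = as.vector(rowsum(rep(1, spikeset$n_spikes), grp)))
}

ppc_from_resultant <- function(R, n) {
  ifelse(n >= 2, (Mod(R)^2 - n) / (n * (n - 1)), NA_real_)
}

#' Attention-condition PPC contrast with trial-label permutation
#'
#' Observed statistic: `PPC(cued) - PPC(noncued)` per frequency.  The null
#' shuffles the condition labels of trials (preserving the condition
#' counts) and recomputes the difference; two-sided p with the +1
#' correction, Holm-corrected across frequencies.
#'
#' @param cued,noncued `spike_phase_set`s on the same frequency grid
#' @param n_perm permutations (1500 by default)
#' @param seed integer seed
#' @return per-frequency `delta`, `p`, `holm_significant`, and the null
#'   matrix
#' @export
condition_ppc_contrast <- function(cued, noncued, n_perm = 1500, seed = 1L) {
  if (isTRUE(cued$empty) || isTRUE(noncued$empty))
    stop2("one condition has no spikes in the window")
  stopifnot(identical(cued$freqs_hz, noncued$freqs_hz))
  set.seed(seed)
  ra <- trial_resultants(cued); rb <- trial_resultants(noncued)
  S <- rbind(ra$S, rb$S)
  n_sp <- c(ra$n, rb$n)
  n_tr <- nrow(S)
  n_a <- nrow(ra$S)
  delta_for <- function(sel_a) {
    Ra <- colSums(S[sel_a, , drop = FALSE])
    Rb <- colSums(S[!sel_a, , drop = FALSE])
    na <- sum(n_sp[sel_a]); nb <- sum(n_sp[!sel_a])
    ppc_from_resultant(Ra, na) - ppc_from_resultant(Rb, nb)
  }
  sel0 <- c(rep(TRUE, n_a), rep(FALSE, n_tr - n_a))
  obs <- delta_for(sel0)
  null <- matrix(NA_real_, n_perm, length(cued$freqs_hz))
  for (i in seq_len(n_perm)) {
    sel <- logical(n_tr); sel[sample.int(n_tr, n_a)] <- TRUE
    null[i, ] <- delta_for(sel)
  }
  p <- vapply(seq_along(obs), function(j)
    perm_pvalue(obs[j], null[, j], "two_sided"), numeric(1))
  structure(list(freqs_hz = cued$freqs_hz, delta = obs, p = p,
                 holm_significant = holm_correct(p), null_delta = null,
                 n_perm = n_perm), class = "ppc_contrast")
}

#' Theta-phase-dependent PPC
#'
#' Computes PPC (per frequency) over spikes whose theta phase lies within
#' each of the 72 overlapping 180-degree theta bins, reduces each
#' function to its one-cycle sine amplitude, and tests it against a null
#' that shuffles spikes' theta-phase assignments.
#'
#' @param spikeset a `spike_phase_set` at the higher frequencies (9-60 Hz)
#' @param theta_phases_at_spikes theta phase (radians) of each spike
#' @param n_perm permutations
#' @param seed integer seed
#' @param min_spikes_per_bin bins with fewer spikes are flagged; more than
#'   4 flagged bins refuse
#' @return per-frequency `amplitude`, `preferred_phase_deg`, `p`,
#'   `holm_significant`, plus the binned PPC matrix (72 x freq)
#' @export
theta_dependent_ppc <- function(spikeset, theta_phases_at_spikes,
                                n_perm = 1500, seed = 1L,
                                min_spikes_per_bin = 10) {
  stopifnot(length(theta_phases_at_spikes) == spikeset$n_spikes)
  set.seed(seed)
  E <- exp(1i * spikeset$phases)
  C <- boxcar_matrix()
  binned_amp <- function(fb) {
    counts <- numeric(N_PHASE_BINS)
    tab <- table(factor(fb, levels = 0:(N_PHASE_BINS - 1)))
    counts[] <- as.numeric(tab)
    Sre <- matrix(0, N_PHASE_BINS, ncol(E))
    Sim <- matrix(0, N_PHASE_BINS, ncol(E))
    agg_re <- rowsum(Re(E), fb); agg_im <- rowsum(Im(E), fb)
    idx <- as.integer(rownames(agg_re)) + 1L
    Sre[idx, ] <- agg_re; Sim[idx, ] <- agg_im
    n_k <- drop(C %*% counts)
    R2 <- (C %*% Sre)^2 + (C %*% Sim)^2
    P <- (R2 - n_k) / (n_k * (n_k - 1))
    P[n_k < min_spikes_per_bin, ] <- NaN
    ft <- sine_fit_matrix(P)
    list(P = P, ft = ft)
  }
  fb0 <- fine_bin(theta_phases_at_spikes)
  obs <- binned_amp(fb0)
  null <- matrix(NA_real_, n_perm, ncol(E))
  for (i in seq_len(n_perm)) {
    null[i, ] <- binned_amp(fb0[sample.int(length(fb0))])$ft$amplitude
  }
  p <- vapply(seq_len(ncol(E)), function(j)
    (1 + sum(null[, j] >= obs$ft$amplitude[j])) / (n_perm + 1), numeric(1))
  structure(list(freqs_hz = spikeset$freqs_hz,
                 amplitude = obs$ft$amplitude,
                 preferred_phase_deg = obs$ft$preferred_phase_deg,
                 binned_ppc = obs$P, p = p,
                 holm_significant = holm_correct(p),
                 null_amplitude = null, n_perm = n_perm),
            class = "theta_ppc")
}

#' Power-equating stratified theta-bin PPC
#'
#' Compares PPC between spikes in the theta half-cycles centered at 90 and
#' 270 degrees while equating the distribution of alpha/low-beta power at
#' the spike times, removing the power->phase-reliability confound.  The
#' subsample differs on each run, so the procedure is repeated `n_iter`
#' times and the mean and SD across iterations are reported.
#'
#' @param spike_phases higher-frequency phases, one per spike (single
#'   frequency) or n_spikes x freq matrix
#' @param theta_phases theta phase per spike, radians
#' @param power_at_spikes alpha/low-beta power per spike
#' @param n_iter stratification repetitions (1500 by default)
#' @param n_bins histogram bins for power equating
#' @param centers_deg the two theta-bin centers
#' @param seed integer seed
#' @return list with per-bin mean/SD of PPC across iterations and the
#'   per-iteration difference (`bin1 - bin2`)
#' @export
stratified_theta_ppc <- function(spike_phases, theta_phases, power_at_spikes,
                                 n_iter = 1500, n_bins = 20,
                                 centers_deg = c(90, 270), seed = 1L) {
  ph <- as.matrix(spike_phases)
  in_bin <- function(center) {
    abs(wrap_pi(theta_phases - deg2rad(center))) < pi / 2
  }
  g1 <- which(in_bin(centers_deg[1]))
  g2 <- which(in_bin(centers_deg[2]))
  seeds <- derive_seeds(seed, n_iter)
  ppc1 <- ppc2 <- matrix(NA_real_, n_iter, ncol(ph))
  dropped <- 0L
  for (i in seq_len(n_iter)) {
    st <- tryCatch(stratify(power_at_spikes[g1], power_at_spikes[g2],
                            n_bins = n_bins, seed = seeds[i]),
                   error = function(e) NULL)
    if (is.null(st) || length(st$kept_a) < 2) { dropped <- dropped + 1L; next }
    k1 <- g1[st$kept_a]; k2 <- g2[st$kept_b]
    ppc1[i, ] <- apply(ph[k1, , drop = FALSE], 2, ppc)
    ppc2[i, ] <- apply(ph[k2, , drop = FALSE], 2, ppc)
  }
  if (dropped > n_iter / 2)
    stop2("more than half of the stratification iterations were empty")
  diff <- ppc1 - ppc2
  list(centers_deg = centers_deg,
       mean_bin1 = colMeans(ppc1, na.rm = TRUE),
       sd_bin1 = apply(ppc1, 2, stats::sd, na.rm = TRUE),
       mean_bin2 = colMeans(ppc2, na.rm = TRUE),
       sd_bin2 = apply(ppc2, 2, stats::sd, na.rm = TRUE),
       mean_diff = colMeans(diff, na.rm = TRUE),
       sd_diff = apply(diff, 2, stats::sd, na.rm = TRUE),
       n_iter = n_iter, n_dropped = dropped)
}
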