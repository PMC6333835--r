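## Phase-amplitude coupling: power sorted into 72 overlapping 180-degree
## phase bins, normalized to percent modulation, reduced to the one-cycle
## sine amplitude, with phase-shuffle permutation nulls.  Used within
## regions (theta phase -> higher-frequency power), between regions
## (9-35 Hz phase -> HFB), and within theta-phase bins (alpha/low-beta
## phase -> gamma power).

#' Phase-binned percent power modulation
#'
#' Pools (trial, time) samples, averages power within each of the 72
#' overlapping 180-degree phase bins, normalizes by subtracting and
#' dividing by the across-bin mean power, multiplies by 100 (percent
#' modulation), and fits the one-cycle sine.
#'
#' @param phases phases, radians: vector or trials x time matrix
#' @param power power values, same shape
#' @param normalize `"percent"` (default) rescales bins to percent
#'   modulation around the across-bin mean; `"none"` keeps raw units —
#'   used for already z-scored quantities such as the HFB envelope, whose
#'   near-zero mean makes a ratio ill-defined
#' @return a `pac_entry`: `binned` (`phase_binned_function`),
#'   `modulation_pct` (percent, or raw units under `"none"`),
#'   `preferred_phase_deg`
#' @export
pac_phase_power <- function(phases, power,
                            normalize = c("percent", "none")) {
  normalize <- match.arg(normalize)
  ph <- as.vector(phases); pw <- as.vector(power)
  stopifnot(length(ph) == length(pw))
  f <- phase_binned_values(ph, pw)
  if (normalize == "percent") {
    m <- mean(f$values[is.finite(f$values)])
    f$values <- (f$values - m) / m * 100
  }
  ft <- one_cycle_sine_amplitude(f)
  structure(list(binned = f, modulation_pct = ft$amplitude,
                 preferred_phase_deg = ft$preferred_phase_deg),
            class = "pac_entry")
}

## Trial-shuffle PAC null: permute whole trials of the phase matrix
## relative to the power matrix, preserving each series' own structure.
pac_permutation <- function(phase_mat, power_mat, n_perm, seed,
                            sample_mask = NULL, normalize = "percent") {
  phase_mat <- as.matrix(phase_mat); power_mat <- as.matrix(power_mat)
  set.seed(seed)
  n <- nrow(phase_mat)
  take <- function(M, mask) if (is.null(mask)) as.vector(M) else M[mask]
  obs <- pac_phase_power(take(phase_mat, sample_mask),
                         take(power_mat, sample_mask), normalize)
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n)
    pm <- phase_mat[idx, , drop = FALSE]
    msk <- if (is.null(sample_mask)) NULL else sample_mask[idx, , drop = FALSE]
    null[i] <- pac_phase_power(take(pm, msk),
                               take(power_mat, msk), normalize)$modulation_pct
  }
  list(entry = obs, null = null,
       p = (1 + sum(null >= obs$modulation_pct)) / (n_perm + 1))
}

#' Within-region PAC: one phase frequency to many power frequencies
#'
#' Links theta phase (5 Hz by default) to power at each higher frequency
#' (9-60 Hz).  The null shuffles the observed phase estimates (whole
#' trials) relative to observed power; Holm correction runs across power
#' frequencies.
#'
#' @param phase_mat trials x time matrix of phases at the phase frequency
#' @param power_list list over power frequencies of trials x time power
#' @param power_freqs labels, Hz
#' @param n_perm permutations
#' @param seed integer seed
#' @return a `pac_map`: per-frequency `modulation_pct`,
#'   `preferred_phase_deg`, `p`, `holm_significant`
#' @export
within_region_pac <- function(phase_mat, power_list, power_freqs,
                              n_perm = 1500, seed = 1L) {
  stopifnot(length(power_list) == length(power_freqs))
  seeds <- derive_seeds(seed, length(power_freqs))
  res <- lapply(seq_along(power_freqs), function(j) {
    pac_permutation(phase_mat, power_list[[j]], n_perm, seeds[j])
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  structure(list(phase_freqs_hz = power_freqs,
                 modulation_pct = vapply(res, function(r)
                   r$entry$modulation_pct, numeric(1)),
                 preferred_phase_deg = vapply(res, function(r)
                   r$entry$preferred_phase_deg, numeric(1)),
                 p = p, holm_significant = holm_correct(p),
                 n_perm = n_perm), class = "pac_map")
}

#' Between-region PAC: oscillatory phase in one region to HFB in the other
#'
#' For each phase frequency (9-35 Hz in 1-Hz steps), couples region A's
#' phase to region B's z-scored high-frequency-band envelope over the
#' pre-target window; trial-shuffle null, Holm across phase frequencies.
#'
#' @param phase_spect `complex_spectrogram` of region A at the phase
#'   frequencies, sampled at the analysis times (e.g., -750 to -200 ms in
#'   10-ms steps)
#' @param hfb an `hfb_series` of region B on the same time grid
#' @param n_perm permutations
#' @param seed integer seed
#' @return a `pac_map` over phase frequencies
#' @export
between_region_pac_hfb <- function(phase_spect, hfb, n_perm = 1500,
                                   seed = 1L) {
  stopifnot(inherits(phase_spect, "complex_spectrogram"),
            inherits(hfb, "hfb_series"))
  if (!isTRUE(all.equal(phase_spect$times_ms, hfb$times_ms)))
    stop2("phase and HFB series are on different time grids")
  seeds <- derive_seeds(seed, length(phase_spect$freqs_hz))
  res <- lapply(seq_along(phase_spect$freqs_hz), function(j) {
    ok <- phase_spect$edge_ok[[j]] & hfb$edge_ok
    pac_permutation(Arg(phase_spect$coef[[j]][, ok, drop = FALSE]),
                    hfb$zscored_hfb[, ok, drop = FALSE],
                    n_perm, seeds[j], normalize = "none")
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  structure(list(phase_freqs_hz = phase_spect$freqs_hz,
                 modulation_pct = vapply(res, function(r)
                   r$entry$modulation_pct, numeric(1)),
                 preferred_phase_deg = vapply(res, function(r)
                   r$entry$preferred_phase_deg, numeric(1)),
                 p = p, holm_significant = holm_correct(p),
                 n_perm = n_perm), class = "pac_map")
}

#' Theta-binned PAC: alpha/low-beta phase to gamma power per theta bin
#'
#' Restricts the pooled (trial, time) samples to moments when theta phase
#' lies within the good (or poor) half-cycle, then runs the full PAC
#' analysis per bin, each with its own trial-shuffle null.
#'
#' @param phase_mat trials x time alpha/low-beta phases
#' @param power_mat trials x time gamma power
#' @param theta_mat trials x time theta phases
#' @param bins a `theta_bin_definition`
#' @param n_perm permutations
#' @param seed integer seed
#' @param min_samples refuse bins with fewer pooled samples
#' @return list `good`/`poor` of `pac_entry` + `p`
#' @export
theta_binned_pac <- function(phase_mat, power_mat, theta_mat, bins,
                             n_perm = 1500, seed = 1L, min_samples = 500) {
  seeds <- derive_seeds(seed, 2)
  out <- list()
  for (b in c("good", "poor")) {
    center <- if (b == "good") bins$good_center_deg else bins$poor_center_deg
    mask <- abs(wrap_pi(as.matrix(theta_mat) - deg2rad(center))) <= pi / 2
    if (sum(mask) < min_samples)
      stop2("theta bin '", b, "' has fewer than ", min_samples, " samples")
    pr <- pac_permutation(phase_mat, power_mat, n_perm,
                          seeds[match(b, c("good", "poor"))],
                          sample_mask = mask)
    out[[b]] <- list(entry = pr$entry, p = pr$p, null = pr$null)
  }
  out
}
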