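## Time-frequency decomposition: complex Morlet spectrograms, Hanning-taper
## FFT power, IRASA fractal/oscillatory separation, and the z-scored
## high-frequency-band (HFB) envelope used as a spiking proxy.

## Build a complex Morlet wavelet at frequency f (Hz).  Normalized so a
## unit-amplitude cosine at f yields |coefficient| ~= 1.
morlet_wavelet <- function(f, rate_hz, n_cycles) {
  sd_t <- n_cycles / (2 * pi * f)            # seconds
  half <- ceiling(3.5 * sd_t * rate_hz)
  t <- (-half:half) / rate_hz
  g <- exp(-t^2 / (2 * sd_t^2))
  w <- exp(2i * pi * f * t) * g
  w / (0.5 * sum(g))
}

reflect_pad <- function(x, pad_l, pad_r) {
  n <- ncol(x)
  left <- x[, rev(seq_len(pad_l)) + 1, drop = FALSE]
  right <- x[, n - seq_len(pad_r), drop = FALSE]
  cbind(left, x, right)
}

#' Complex Morlet wavelet transform
#'
#' Convolves each trial with complex Morlet wavelets.  Edges are
#' reflect-padded; output samples whose wavelet support (+/- 3.5 SD)
#' extends beyond the epoch are flagged as edge-contaminated and should be
#' excluded from statistics.
#'
#' Phase convention: phase 0 at the signal maximum (cosine phase),
#' increasing with time, in `[-pi, pi)`.
#'
#' @param signal an `epoched_signal`
#' @param freqs frequencies, Hz (all below Nyquist)
#' @param n_cycles wavelet width in cycles; scalar or one per frequency
#' @param times_ms optional subset of output times (defaults to every sample)
#' @return a `complex_spectrogram`: `freqs_hz`, `times_ms`, `coef` (list per
#'   frequency of trials x time complex matrices), `edge_ok` (list per
#'   frequency of logical vectors over output times)
#' @export
morlet_transform <- function(signal, freqs, n_cycles = 3, times_ms = NULL) {
  stopifnot(inherits(signal, "epoched_signal"))
  fs <- signal$rate_hz
  if (any(freqs >= fs / 2)) stop2("requested frequency at or above Nyquist")
  if (length(n_cycles) == 1L) n_cycles <- rep(n_cycles, length(freqs))
  x <- signal$samples
  n <- ncol(x)
  t_all <- signal_times(signal)
  if (is.null(times_ms)) {
    sel <- seq_len(n)
  } else {
    sel <- vapply(times_ms, function(tt) which.min(abs(t_all - tt)), 1L)
  }
  out_t <- t_all[sel]

  widest <- ceiling(3.5 * max(n_cycles / (2 * pi * freqs)) * fs) * 2 + 1
  if (widest > 2 * n)
    stop2("epoch too short for the requested cycles at the lowest frequency")

  coef <- vector("list", length(freqs))
  edge_ok <- vector("list", length(freqs))
  for (j in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[j], fs, n_cycles[j])
    half <- (length(w) - 1L) / 2L
    pad <- min(half, n - 1L)
    if (length(sel) <= 20 && half <= n - 1L) {
      # few output times: direct windowed products beat FFT convolution
      xp <- reflect_pad(x, pad, pad)
      cf <- vapply(sel, function(s) {
        seg <- xp[, (s + pad - half):(s + pad + half), drop = FALSE]
        as.vector(seg %*% Conj(w))
      }, complex(nrow(x)))
      coef[[j]] <- matrix(cf, nrow = nrow(x))
      ok_all <- seq_len(n) > half & seq_len(n) <= n - half
      edge_ok[[j]] <- ok_all[sel]
      next
    }
    xp <- reflect_pad(x, pad, pad)
    np <- stats::nextn(ncol(xp) + length(w))
    h <- complex(real = numeric(np))
    h[1:(half + 1)] <- w[(half + 1):length(w)]
    h[(np - half + 1):np] <- w[1:half]
    X <- stats::mvfft(t(cbind(xp, matrix(0, nrow(xp), np - ncol(xp)))))
    H <- stats::fft(h)
    W <- stats::mvfft(X * Conj(H), inverse = TRUE) / np
    full <- t(W)[, pad + seq_len(n), drop = FALSE]
    coef[[j]] <- full[, sel, drop = FALSE]
    ok_all <- seq_len(n) > half & seq_len(n) <= n - half
    edge_ok[[j]] <- ok_all[sel]
  }
  structure(list(freqs_hz = freqs, times_ms = out_t, coef = coef,
                 edge_ok = edge_ok, n_cycles = n_cycles,
                 roi = signal$roi, channel = signal$channel,
                 rate_hz = fs, trial_ids = signal$trial_ids),
            class = "complex_spectrogram")
}

## Hanning-taper one-sided power of a numeric matrix (trials x time), at the
## FFT bin frequencies.  Taper-compensated so a sinusoid of amplitude a has
## peak power a^2 / 2.
taper_power <- function(x, rate_hz) {
  n <- ncol(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  xw <- sweep(x, 2, w, `*`)
  X <- stats::mvfft(t(xw))
  nf <- n %/% 2
  p <- (2 * Mod(X[2:(nf + 1), , drop = FALSE]) / sum(w))^2 / 2
  list(freqs = seq_len(nf) * rate_hz / n, power = rowMeans(p))
}

#' Hanning-window FFT power spectrum
#'
#' Trial-averaged, taper-compensated power at the FFT bin frequencies of the
#' analysis window (a 500 ms window at 1000 Hz gives 2 Hz resolution),
#' restricted to `freq_range` (3-60 Hz by default; higher frequencies are
#' treated as broadband, not oscillatory).
#'
#' @param signal an `epoched_signal`
#' @param window `(start_ms, stop_ms)` half-open analysis window
#' @param freq_range reported frequency range, Hz
#' @return a `power_spectrum` with `total_power` (fractal/residual NA until
#'   [irasa()] fills them)
#' @export
hanning_fft_power <- function(signal, window, freq_range = c(3, 60)) {
  seg <- epoch_window(signal, window[1], window[2])
  n <- ncol(seg$samples)
  if (n < signal$rate_hz / freq_range[1])
    stop2("window shorter than one cycle of the lowest requested frequency")
  tp <- taper_power(seg$samples, signal$rate_hz)
  keep <- tp$freqs >= freq_range[1] & tp$freqs <= freq_range[2]
  structure(list(freqs_hz = tp$freqs[keep], total_power = tp$power[keep],
                 fractal_power = rep(NA_real_, sum(keep)),
                 oscillatory_residual = rep(NA_real_, sum(keep)),
                 window = window, taper = "hanning"),
            class = "power_spectrum")
}

## Stretch (h > 1) or compress (h < 1) each trial in time by cubic spline
## interpolation, keeping the nominal sampling rate.
resample_by <- function(x, h) {
  n <- ncol(x)
  idx <- seq(1, n, by = 1 / h)
  t(apply(x, 1, function(r) stats::spline(seq_len(n), r, xout = idx)$y))
}

#' IRASA fractal / oscillatory decomposition
#'
#' Irregular-resampling auto-spectral analysis: resampling the signal by
#' pairwise non-integer factors h and 1/h shifts oscillatory peaks but
#' leaves the scale-free 1/f component in place.  The fractal spectrum is
#' the median across h of the geometric mean of the h- and 1/h-resampled
#' power spectra; the oscillatory residual is total minus fractal
#' (`total = fractal + residual` holds exactly by construction).
#'
#' @param signal an `epoched_signal`
#' @param window `(start_ms, stop_ms)` analysis window
#' @param h_set resampling factors, all > 1 and non-integer
#' @param freq_range reported range, Hz
#' @param min_delay_ms trials whose relevant delay is below this are meant to
#'   be excluded upstream; retained here as documentation of the contract
#' @return a `power_spectrum` with total, fractal, and residual components
#' @export
irasa <- function(signal, window, h_set = seq(1.1, 1.9, by = 0.05),
                  freq_range = c(3, 60), min_delay_ms = 750) {
  if (any(h_set <= 1) || any(abs(h_set - round(h_set)) < 1e-9))
    stop2("h_set factors must be non-integer and > 1")
  ps <- hanning_fft_power(signal, window, freq_range)
  seg <- epoch_window(signal, window[1], window[2])
  if (all(seg$samples == 0)) {
    ps$fractal_power <- numeric(length(ps$freqs_hz))
    ps$oscillatory_residual <- numeric(length(ps$freqs_hz))
    return(ps)
  }
  frac_h <- matrix(NA_real_, length(h_set), length(ps$freqs_hz))
  for (i in seq_along(h_set)) {
    h <- h_set[i]
    up <- taper_power(resample_by(seg$samples, h), signal$rate_hz)
    dn <- taper_power(resample_by(seg$samples, 1 / h), signal$rate_hz)
    pu <- stats::approx(up$freqs, up$power, xout = ps$freqs_hz, rule = 2)$y
    pd <- stats::approx(dn$freqs, dn$power, xout = ps$freqs_hz, rule = 2)$y
    frac_h[i, ] <- sqrt(pu * pd)
  }
  ps$fractal_power <- apply(frac_h, 2, stats::median)
  ps$oscillatory_residual <- ps$total_power - ps$fractal_power
  ps
}

#' Fit the log-log slope of a fractal power spectrum
#'
#' @param ps a `power_spectrum` from [irasa()]
#' @param component which component to fit
#' @return least-squares slope of log10(power) on log10(frequency)
#' @export
fractal_slope <- function(ps, component = "fractal_power") {
  y <- ps[[component]]
  ok <- y > 0
  stats::coef(stats::lm(log10(y[ok]) ~ log10(ps$freqs_hz[ok])))[[2]]
}

#' High-frequency-band (80-200 Hz) envelope, z-scored per sub-band
#'
#' Power at each 10-Hz step is z-scored against its own pre-cue baseline
#' distribution (pooled over trials and baseline times) *before* averaging
#' across steps, which neutralizes the 1/f power drop-off across the band.
#'
#' @param spect a `complex_spectrogram` computed at 80, 90, ..., 200 Hz
#' @param baseline_window `(start_ms, stop_ms)` baseline span within the
#'   spectrogram's times
#' @return an `hfb_series`: `times_ms`, `zscored_hfb` (trials x time)
#' @export
hfb_envelope <- function(spect, baseline_window) {
  stopifnot(inherits(spect, "complex_spectrogram"))
  bl <- spect$times_ms >= baseline_window[1] &
    spect$times_ms < baseline_window[2]
  if (!any(bl)) stop2("baseline window outside the spectrogram epoch")
  z_sum <- 0
  for (j in seq_along(spect$freqs_hz)) {
    p <- Mod(spect$coef[[j]])^2
    ok <- bl & spect$edge_ok[[j]]
    base <- p[, ok, drop = FALSE]
    mu <- mean(base); sdv <- stats::sd(as.vector(base))
    if (sdv == 0) stop2("degenerate baseline (zero variance)")
    z_sum <- z_sum + (p - mu) / sdv
  }
  structure(list(times_ms = spect$times_ms,
                 zscored_hfb = z_sum / length(spect$freqs_hz),
                 band = range(spect$freqs_hz),
                 baseline_window = baseline_window,
                 edge_ok = Reduce(`&`, spect$edge_ok)),
            class = "hfb_series")
}
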