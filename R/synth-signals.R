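## LFP / spike / coupled-region generators.  All ground-truth parameters
## travel with the generated objects (a `truth` element) so recovery tests
## never re-derive truth from the data.

#' Signal configuration for the synthetic LFP generator
#'
#' The generated epoch is: 1/f^chi fractal background + a theta sinusoid
#' with random per-trial phase + an alpha/low-beta carrier whose envelope is
#' gated by theta phase (depth `pac_depth`) + optional alpha-gated gamma +
#' white noise.  Amplitudes are microvolts.
#'
#' @param fractal_exponent chi in power ~ 1/f^chi
#' @param fractal_sd SD of the fractal background, uV
#' @param theta_freq Hz (5 by default)
#' @param theta_amp theta sinusoid amplitude, uV
#' @param alpha_band Hz pair for the theta-gated carrier (10-20 default);
#'   each trial draws its carrier frequency uniformly within the band
#' @param alpha_amp carrier amplitude, uV
#' @param pac_depth theta->alpha envelope modulation depth in [0,1]
#' @param pac_preferred_phase_deg theta phase (deg) of maximal alpha envelope
#' @param gamma_band Hz pair for the alpha-gated gamma component
#' @param gamma_amp gamma amplitude, uV
#' @param gamma_pac_depth alpha->gamma envelope modulation depth in [0,1]
#' @param gamma_preferred_phase_deg alpha phase (deg) of maximal gamma
#' @param hfb_amp amplitude of a broadband 80-200 Hz component, uV
#' @param hfb_pac_depth modulation depth of the broadband envelope by an
#'   externally supplied phase (see `ext_phase` in [synthesize_lfp()])
#' @param noise_sd white measurement noise SD, uV
#' @param rate_hz sampling rate (1000 native)
#' @param seed integer seed
#' @export
signal_config <- function(fractal_exponent = 1.5, fractal_sd = 5,
                          theta_freq = 5, theta_amp = 10,
                          alpha_band = c(10, 20), alpha_amp = 5,
                          pac_depth = 0, pac_preferred_phase_deg = 90,
                          gamma_band = c(30, 48), gamma_amp = 0,
                          gamma_pac_depth = 0, gamma_preferred_phase_deg = 0,
                          hfb_amp = 0, hfb_pac_depth = 0,
                          noise_sd = 1, rate_hz = 1000, seed = 1L) {
  depths <- c(pac_depth, gamma_pac_depth, hfb_pac_depth)
  if (any(depths < 0 | depths > 1)) stop2("coupling depths must lie in [0,1]")
  for (band in list(alpha_band, gamma_band))
    if (any(band <= 0) || any(band >= rate_hz / 2))
      stop2("bands must lie within (0, rate/2)")
  structure(as.list(environment()), class = "signal_config")
}

## Frequency-domain shaped 1/f^chi noise, one trial per row.
fractal_noise <- function(n_trials, n_samples, rate_hz, chi, sd_target) {
  nf <- n_samples %/% 2
  f <- seq_len(nf) * rate_hz / n_samples
  amp <- f^(-chi / 2)
  out <- matrix(0, n_trials, n_samples)
  for (i in seq_len(n_trials)) {
    ph <- stats::runif(nf, 0, 2 * pi)
    spec <- complex(modulus = amp, argument = ph)
    full <- complex(real = numeric(n_samples))
    full[2:(nf + 1)] <- spec
    if (n_samples %% 2 == 0) {
      full[n_samples:(nf + 2)] <- Conj(spec[1:(nf - 1)])
      full[nf + 1] <- complex(real = Mod(spec[nf]))  # Nyquist bin real
    } else {
      full[n_samples:(nf + 2)] <- Conj(spec)
    }
    x <- Re(stats::fft(full, inverse = TRUE)) / n_samples
    out[i, ] <- x / stats::sd(x) * sd_target
  }
  out
}

#' Synthesize per-trial LFP epochs
#'
#' @param trials a `trial_table`
#' @param config a [signal_config()]
#' @param t0_ms,stop_ms epoch span relative to the alignment event
#'   (half-open, default `[-1000, 250)` around the target)
#' @param alignment_event `"cue"` or `"target"`
#' @param roi,channel labels
#' @param ext_phase optional trials x time matrix of external phases
#'   (radians) that modulates the broadband 80-200 Hz envelope with depth
#'   `hfb_pac_depth` (between-region PAC ground truth)
#' @return an `epoched_signal` with a `truth` element recording the
#'   per-trial theta phase offset, carrier frequency/phase, and config
#' @export
synthesize_lfp <- function(trials, config, t0_ms = -1000, stop_ms = 250,
                           alignment_event = "target",
                           roi = "roi", channel = "ch1", ext_phase = NULL) {
  stopifnot(inherits(config, "signal_config"))
  set.seed(config$seed)
  n <- nrow(trials)
  fs <- config$rate_hz
  ns <- round((stop_ms - t0_ms) * fs / 1000)
  t_ms <- t0_ms + (seq_len(ns) - 1) * 1000 / fs
  t_s <- t_ms / 1000

  x <- fractal_noise(n, ns, fs, config$fractal_exponent, config$fractal_sd)

  theta0 <- stats::runif(n, -pi, pi)
  carrier_f <- stats::runif(n, config$alpha_band[1], config$alpha_band[2])
  carrier0 <- stats::runif(n, -pi, pi)
  gamma_f <- stats::runif(n, config$gamma_band[1], config$gamma_band[2])
  gamma0 <- stats::runif(n, -pi, pi)

  for (i in seq_len(n)) {
    phi_th <- 2 * pi * config$theta_freq * t_s + theta0[i]
    xi <- config$theta_amp * cos(phi_th)
    phi_a <- 2 * pi * carrier_f[i] * t_s + carrier0[i]
    env_a <- 1 + config$pac_depth *
      cos(phi_th - deg2rad(config$pac_preferred_phase_deg))
    xi <- xi + config$alpha_amp * env_a * cos(phi_a)
    if (config$gamma_amp > 0) {
      env_g <- 1 + config$gamma_pac_depth *
        cos(phi_a - deg2rad(config$gamma_preferred_phase_deg))
      xi <- xi + config$gamma_amp * env_g * cos(2 * pi * gamma_f[i] * t_s + gamma0[i])
    }
    x[i, ] <- x[i, ] + xi
  }
  if (config$hfb_amp > 0) {
    bb <- band_noise(n, ns, fs, c(80, 200))
    if (!is.null(ext_phase) && config$hfb_pac_depth > 0) {
      bb <- bb * (1 + config$hfb_pac_depth * cos(ext_phase))
    }
    x <- x + config$hfb_amp * bb
  }
  x <- x + matrix(stats::rnorm(n * ns, sd = config$noise_sd), n, ns)

  sig <- epoched_signal(x, fs, t0_ms, trials$trial_id, roi, channel,
                        alignment_event)
  sig$truth <- list(theta_freq = config$theta_freq, theta_phase0 = theta0,
                    carrier_freq = carrier_f, carrier_phase0 = carrier0,
                    gamma_freq = gamma_f, gamma_phase0 = gamma0,
                    config = unclass(config))
  sig
}

## Unit-SD band-limited Gaussian noise (frequency-domain mask).
band_noise <- function(n_trials, n_samples, rate_hz, band) {
  f <- abs(seq(0, rate_hz - rate_hz / n_samples, length.out = n_samples))
  f <- pmin(f, rate_hz - f)
  mask <- f >= band[1] & f <= band[2]
  out <- matrix(0, n_trials, n_samples)
  for (i in seq_len(n_trials)) {
    spec <- stats::fft(stats::rnorm(n_samples))
    spec[!mask] <- 0
    x <- Re(stats::fft(spec, inverse = TRUE)) / n_samples
    out[i, ] <- x / stats::sd(x)
  }
  out
}

#' True per-trial oscillatory phase of a synthetic LFP
#'
#' Evaluates the generator's analytic phase (theta or the alpha/low-beta
#' carrier) at the given times; never re-estimated from the data.
#'
#' @param lfp an `epoched_signal` from [synthesize_lfp()]
#' @param t_ms scalar time or vector of times (ms)
#' @param component `"theta"` or `"carrier"`
#' @return if `t_ms` is scalar, a vector of per-trial phases; otherwise a
#'   trials x time matrix (radians, cosine convention)
#' @export
true_phase <- function(lfp, t_ms, component = c("theta", "carrier")) {
  component <- match.arg(component)
  truth <- lfp$truth
  if (is.null(truth)) stop2("lfp carries no generator ground truth")
  if (component == "theta") {
    f <- truth$theta_freq; ph0 <- truth$theta_phase0
  } else {
    f <- truth$carrier_freq; ph0 <- truth$carrier_phase0
  }
  if (length(t_ms) == 1L) return(wrap_pi(2 * pi * f * t_ms / 1000 + ph0))
  ph <- outer(ph0, 2 * pi * t_ms / 1000, function(p0, w) p0) +
    outer(if (length(f) == 1L) rep(f, length(ph0)) else f, t_ms / 1000) * 2 * pi
  wrap_pi(ph)
}

#' Coupling configuration: directed VAR influence and spike-phase coupling
#'
#' @param var_coefficients array `[n_region, n_region, n_lag]`;
#'   `var_coefficients[i, j, k]` is the influence of region j at lag k on
#'   region i.  Must imply a stable companion matrix.
#' @param spike_coupling list per unit: `target_band` (Hz pair),
#'   `kappa` (von Mises concentration), `preferred_phase_deg`, and optional
#'   `gate` = list(`phase_deg`) restricting coupling to the theta half-cycle
#'   centered there
#' @param seed integer seed
#' @export
coupling_config <- function(var_coefficients = NULL, spike_coupling = NULL,
                            seed = 1L) {
  if (!is.null(var_coefficients)) {
    if (companion_radius(var_coefficients) >= 1)
      stop2("VAR coefficients imply an unstable model (spectral radius >= 1)")
  }
  if (!is.null(spike_coupling)) {
    for (sc in spike_coupling)
      if (!is.null(sc$kappa) && sc$kappa < 0) stop2("kappa must be >= 0")
  }
  structure(list(var_coefficients = var_coefficients,
                 spike_coupling = spike_coupling, seed = seed),
            class = "coupling_config")
}

companion_radius <- function(A) {
  k <- dim(A)[1]; p <- dim(A)[3]
  comp <- matrix(0, k * p, k * p)
  for (l in seq_len(p)) comp[1:k, ((l - 1) * k + 1):(l * k)] <- A[, , l]
  if (p > 1) comp[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Synthesize a phase-coupled spike train
#'
#' Inhomogeneous Poisson spikes with intensity proportional to
#' `exp(kappa * cos(phase(t) - preferred))`, normalized so the epoch-mean
#' rate equals `mean_rate_hz`.  With a theta-gate, coupling applies only
#' while the generator's theta phase lies within +/-90 deg of the gate
#' center; elsewhere the process is homogeneous at `mean_rate_hz`.
#'
#' @param lfp an `epoched_signal` from [synthesize_lfp()] (supplies the
#'   analytic carrier and theta phases)
#' @param config a [coupling_config()] with one `spike_coupling` entry
#' @param mean_rate_hz target mean firing rate
#' @param unit_id,roi labels
#' @return a `spike_train`
#' @export
synthesize_spikes <- function(lfp, config, mean_rate_hz = 20,
                              unit_id = "u1", roi = lfp$roi) {
  stopifnot(inherits(config, "coupling_config"))
  sc <- config$spike_coupling[[1]]
  if (is.null(sc)) stop2("config carries no spike_coupling entry")
  if (sc$kappa < 0) stop2("kappa must be >= 0")
  set.seed(config$seed)
  t_ms <- signal_times(lfp)
  dt <- 1 / lfp$rate_hz
  n <- nrow(lfp$samples)
  mu <- deg2rad(sc$preferred_phase_deg %||% 0)
  band_is_theta <- !is.null(lfp$truth) &&
    lfp$truth$theta_freq >= sc$target_band[1] &&
    lfp$truth$theta_freq <= sc$target_band[2]
  spikes <- vector("list", n)
  for (i in seq_len(n)) {
    if (band_is_theta) {
      phi <- 2 * pi * lfp$truth$theta_freq * t_ms / 1000 +
        lfp$truth$theta_phase0[i]
    } else {
      phi <- 2 * pi * lfp$truth$carrier_freq[i] * t_ms / 1000 +
        lfp$truth$carrier_phase0[i]
    }
    lam <- exp(sc$kappa * cos(phi - mu)) / besselI(sc$kappa, 0)
    if (!is.null(sc$gate)) {
      phi_th <- 2 * pi * lfp$truth$theta_freq * t_ms / 1000 +
        lfp$truth$theta_phase0[i]
      open <- abs(wrap_pi(phi_th - deg2rad(sc$gate$phase_deg))) <= pi / 2
      lam[!open] <- 1
    }
    lam <- lam * mean_rate_hz
    fire <- stats::runif(length(lam)) < lam * dt
    spikes[[i]] <- sort(t_ms[fire] + stats::runif(sum(fire), -0.5, 0.5) *
                          1000 * dt)
  }
  spike_train(spikes, lfp$trial_ids, unit_id, roi, lfp$alignment_event)
}

#' Synthesize directionally coupled multi-region LFP epochs
#'
#' Per trial, a multivariate series is simulated from the configured VAR
#' driven by unit-variance Gaussian innovations (with burn-in).  Cross-region
#' coefficients can be gated per trial (e.g., active only on "good"
#' theta-phase trials) to create phase-dependent directed influence.
#'
#' @param trials a `trial_table`
#' @param config a [coupling_config()] with `var_coefficients`
#' @param n_samples epoch length in samples
#' @param rate_hz sampling rate of the generated series
#' @param t0_ms time of the first sample
#' @param gate_trials optional logical per trial; where FALSE, off-diagonal
#'   VAR coefficients are zeroed for that trial
#' @param roi_names labels, default region1..regionK
#' @return named list of `epoched_signal`, one per region
#' @export
synthesize_coupled_regions <- function(trials, config, n_samples = 250,
                                       rate_hz = 250, t0_ms = -500,
                                       gate_trials = NULL,
                                       roi_names = NULL) {
  stopifnot(inherits(config, "coupling_config"))
  A <- config$var_coefficients
  if (is.null(A)) stop2("config carries no var_coefficients")
  if (companion_radius(A) >= 1) stop2("unstable VAR")
  set.seed(config$seed)
  k <- dim(A)[1]; p <- dim(A)[3]
  n <- nrow(trials)
  if (is.null(roi_names)) roi_names <- paste0("region", seq_len(k))
  A_diag <- A
  for (l in seq_len(p)) A_diag[, , l] <- diag(diag(A[, , l]), k, k)
  burn <- 10 * p + 50
  out <- array(0, c(n, n_samples, k))
  for (i in seq_len(n)) {
    Ai <- if (!is.null(gate_trials) && !gate_trials[i]) A_diag else A
    x <- matrix(0, k, n_samples + burn)
    eps <- matrix(stats::rnorm(k * (n_samples + burn)), k)
    for (t in (p + 1):(n_samples + burn)) {
      acc <- eps[, t]
      for (l in seq_len(p)) acc <- acc + Ai[, , l] %*% x[, t - l]
      x[, t] <- acc
    }
    out[i, , ] <- t(x[, burn + seq_len(n_samples)])
  }
  sigs <- lapply(seq_len(k), function(j) {
    epoched_signal(out[, , j], rate_hz, t0_ms, trials$trial_id,
                   roi = roi_names[j], channel = "ch1",
                   alignment_event = "target")
  })
  names(sigs) <- roi_names
  sigs
}
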