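# Shared fixtures, all generated in code.

# A cosine-only epoched signal (trials identical), for analytic checks.
cosine_signal <- function(freq_hz, n_trials = 3, t0_ms = -1000,
                          stop_ms = 250, rate_hz = 1000, amp = 1,
                          phase0 = 0) {
  t <- seq(t0_ms, stop_ms - 1000 / rate_hz, by = 1000 / rate_hz) / 1000
  x <- matrix(rep(amp * cos(2 * pi * freq_hz * t + phase0), n_trials),
              n_trials, byrow = TRUE)
  epoched_signal(x, rate_hz, t0_ms, seq_len(n_trials))
}

# Minimal valid trial table with n rows.
tiny_trials <- function(n = 4) {
  generate_trials(task_config(n_trials = n, seed = 99))
}

# Multi-trial VAR simulation used by several Granger tests:
# Y_t = c * X_{t-1} + eps_y, X white.
lagged_pair <- function(n_trials, n_samples, c_lag = 1, seed = 1) {
  set.seed(seed)
  X <- array(0, c(n_trials, n_samples, 2))
  for (i in seq_len(n_trials)) {
    x <- rnorm(n_samples)
    y <- c(0, c_lag * x[-n_samples]) + rnorm(n_samples)
    X[i, , 1] <- x; X[i, , 2] <- y
  }
  X
}

# Chain X -> Z -> Y with no direct X -> Y link.
chain_triple <- function(n_trials, n_samples, seed = 1) {
  set.seed(seed)
  X <- array(0, c(n_trials, n_samples, 3))
  for (i in seq_len(n_trials)) {
    x <- rnorm(n_samples)
    z <- c(0, x[-n_samples]) + rnorm(n_samples)
    y <- c(0, z[-n_samples]) + rnorm(n_samples)
    X[i, , 1] <- x; X[i, , 2] <- y; X[i, , 3] <- z
  }
  X
}
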