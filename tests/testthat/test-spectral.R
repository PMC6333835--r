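test_that("Morlet phase follows the analytic ramp of a pure cosine", {
  sig <- cosine_signal(10, n_trials = 2)
  sp <- morlet_transform(sig, 10, n_cycles = 3)
  mid <- which(sp$edge_ok[[1]])
  ph <- Arg(sp$coef[[1]][1, mid])
  dph <- wrap_pi(diff(ph))
  expect_lt(max(abs(dph - 2 * pi * 10 / 1000)), 0.01)
  # phase 0 at the cosine maximum (t = 0), +pi/2 a quarter cycle later
  i0 <- which.min(abs(sp$times_ms - 0))
  expect_lt(abs(Arg(sp$coef[[1]][1, i0])), 0.05)
  i25 <- which.min(abs(sp$times_ms - 25))
  expect_lt(abs(Arg(sp$coef[[1]][1, i25]) - pi / 2), 0.05)
})

test_that("Morlet amplitude is frequency selective and linear", {
  sig <- cosine_signal(10, n_trials = 1)
  sp <- morlet_transform(sig, c(10, 20), n_cycles = 7)
  i0 <- which.min(abs(sp$times_ms - 0))
  a10 <- Mod(sp$coef[[1]][1, i0]); a20 <- Mod(sp$coef[[2]][1, i0])
  expect_gt(a10 / a20, 10)
  # response at the target frequency matches the wavelet's own frequency
  # response predicted from its Gaussian envelope
  expect_equal(a10, 1, tolerance = 0.01)
  zero <- sig; zero$samples[] <- 0
  spz <- morlet_transform(zero, 10, n_cycles = 7)
  expect_true(all(Mod(spz$coef[[1]]) == 0))
  expect_error(morlet_transform(sig, 600), "Nyquist")
})

test_that("the fast single-time Morlet path agrees with full convolution", {
  set.seed(8)
  x <- matrix(rnorm(3 * 1250), 3)
  sig <- epoched_signal(x, 1000, -1000, 1:3)
  full <- morlet_transform(sig, c(8, 23), n_cycles = 3)
  fast <- morlet_transform(sig, c(8, 23), n_cycles = 3, times_ms = -250)
  i <- which.min(abs(full$times_ms - (-250)))
  for (j in 1:2)
    expect_equal(fast$coef[[j]][, 1], full$coef[[j]][, i], tolerance = 1e-9)
})

test_that("Hanning FFT power peaks at the right bin and scales as amplitude squared", {
  sig <- cosine_signal(10, n_trials = 1, t0_ms = -600, stop_ms = 100)
  ps <- hanning_fft_power(sig, c(-500, 0))
  expect_equal(ps$freqs_hz[which.max(ps$total_power)], 10)
  sig2 <- cosine_signal(10, n_trials = 1, t0_ms = -600, stop_ms = 100,
                        amp = 2)
  ps2 <- hanning_fft_power(sig2, c(-500, 0))
  expect_equal(max(ps2$total_power) / max(ps$total_power), 4,
               tolerance = 0.01)
  expect_error(hanning_fft_power(sig, c(-100, 0)), "one cycle")
})

test_that("white-noise Hanning spectra are flat after trial averaging", {
  set.seed(12)
  x <- matrix(rnorm(500 * 600), 500)
  sig <- epoched_signal(x, 1000, -600, 1:500)
  ps <- hanning_fft_power(sig, c(-500, 0))
  expect_lt(max(ps$total_power) / min(ps$total_power), 3)
})

test_that("IRASA separates fractal slope and oscillatory peaks", {
  tr <- tiny_trials(200)
  cfg <- signal_config(fractal_exponent = 1.5, fractal_sd = 5,
                       theta_amp = 0, alpha_amp = 0, noise_sd = 0, seed = 4)
  lfp <- synthesize_lfp(tr, cfg, t0_ms = -1000, stop_ms = 0)
  ps <- irasa(lfp, c(-1000, 0))
  expect_lt(abs(fractal_slope(ps) + 1.5), 0.15)
  # identity total = fractal + residual holds exactly
  expect_equal(ps$total_power, ps$fractal_power + ps$oscillatory_residual,
               tolerance = 1e-12)
  # pure fractal input: residual small relative to fractal everywhere
  expect_lt(max(abs(ps$oscillatory_residual) / ps$fractal_power), 0.2)
  # fractal + sinusoid: residual maximal at the injected frequency
  cfg2 <- signal_config(fractal_exponent = 1.5, fractal_sd = 5,
                        theta_freq = 10, theta_amp = 6, alpha_amp = 0,
                        noise_sd = 0, seed = 5)
  lfp2 <- synthesize_lfp(tr, cfg2, t0_ms = -1000, stop_ms = 0)
  ps2 <- irasa(lfp2, c(-1000, 0))
  expect_equal(ps2$freqs_hz[which.max(ps2$oscillatory_residual)], 10)
  expect_error(irasa(lfp, c(-1000, 0), h_set = c(1.5, 2)), "non-integer")
})

test_that("zero signal gives an all-zero IRASA decomposition", {
  sig <- epoched_signal(matrix(0, 2, 1000), 1000, -1000, 1:2)
  ps <- irasa(sig, c(-1000, 0))
  expect_true(all(ps$total_power == 0))
  expect_true(all(ps$fractal_power == 0))
  expect_true(all(ps$oscillatory_residual == 0))
})

test_that("HFB z-scoring self-baselines to zero and detects amplitude steps", {
  set.seed(30)
  x <- matrix(rnorm(200 * 1000), 200)
  sig <- epoched_signal(x, 1000, -800, 1:200)
  sp <- morlet_transform(sig, seq(80, 200, by = 10), n_cycles = 7)
  hfb <- hfb_envelope(sp, c(-600, -100))
  sel <- hfb$times_ms >= -600 & hfb$times_ms < -100 & hfb$edge_ok
  expect_lt(abs(mean(hfb$zscored_hfb[, sel])), 0.05)
  # doubling broadband amplitude after the baseline drives z positive
  x2 <- x
  post <- seq(701, 1000)  # times >= -100 ms
  x2[, post] <- 2 * x2[, post]
  sig2 <- epoched_signal(x2, 1000, -800, 1:200)
  sp2 <- morlet_transform(sig2, seq(80, 200, by = 10), n_cycles = 7)
  hfb2 <- hfb_envelope(sp2, c(-600, -100))
  late <- hfb2$times_ms >= -50 & hfb2$edge_ok
  expect_gt(mean(hfb2$zscored_hfb[, late]), 1)
  expect_error(hfb_envelope(sp, c(500, 600)), "baseline")
})

test_that("a band-limited 30 Hz oscillation does not leak into the HFB proxy", {
  set.seed(31)
  x <- matrix(rnorm(100 * 1000), 100)
  t <- seq(-800, 199) / 1000
  x30 <- x + matrix(rep(3 * cos(2 * pi * 30 * t), 100), 100, byrow = TRUE)
  hf <- function(m) {
    sig <- epoched_signal(m, 1000, -800, 1:100)
    sp <- morlet_transform(sig, seq(80, 200, by = 10), n_cycles = 7)
    hfb <- hfb_envelope(sp, c(-600, -100))
    mean(hfb$zscored_hfb[, hfb$edge_ok])
  }
  expect_lt(abs(hf(x30) - hf(x)), 0.1)
})

test_that("phase estimates are invariant to amplitude scaling", {
  set.seed(9)
  x <- matrix(rnorm(2 * 1000), 2)
  a <- epoched_signal(x, 1000, -800, 1:2)
  b <- epoched_signal(10 * x, 1000, -800, 1:2)
  pa <- morlet_transform(a, 12, n_cycles = 3, times_ms = -400)
  pb <- morlet_transform(b, 12, n_cycles = 3, times_ms = -400)
  expect_equal(Arg(pa$coef[[1]]), Arg(pb$coef[[1]]), tolerance = 1e-9)
})
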