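test_that("the one-cycle sine fit is exact on its own grid", {
  th <- deg2rad(phase_bin_centers())
  ft <- one_cycle_sine_amplitude(5 + 2 * cos(th - deg2rad(40)))
  expect_equal(ft$amplitude, 2, tolerance = 1e-12)
  expect_equal(ft$preferred_phase_deg, 40, tolerance = 1e-9)
  expect_equal(ft$mean_level, 5, tolerance = 1e-12)
  # constant input has zero amplitude; a two-cycle input is orthogonal
  expect_equal(one_cycle_sine_amplitude(rep(3, 72))$amplitude, 0,
               tolerance = 1e-12)
  expect_equal(one_cycle_sine_amplitude(cos(2 * th))$amplitude, 0,
               tolerance = 1e-12)
  # refitting the fitted cosine is idempotent
  fitted <- ft$mean_level + ft$amplitude * cos(th - deg2rad(ft$preferred_phase_deg))
  ft2 <- one_cycle_sine_amplitude(fitted)
  expect_equal(ft2$amplitude, ft$amplitude, tolerance = 1e-12)
  expect_error(one_cycle_sine_amplitude(c(rep(NaN, 6), rep(1, 66))),
               "flagged")
})

test_that("phase binning uses 72 overlapping half-open 180-degree bins", {
  f <- phase_binned_values(deg2rad(c(0, 90)), c(1, 0))
  expect_length(f$values, 72)
  # each trial contributes to exactly 36 bins
  expect_equal(sum(f$n_per_bin), 2 * 36)
  # the bin at 0 deg pools across the wrap
  f2 <- phase_binned_values(deg2rad(c(350, 10)), c(1, 1))
  expect_equal(f2$values[1], 1)
  # all-hit input gives the constant function 1
  set.seed(1)
  f3 <- phase_binned_hit_rate(runif(300, -pi, pi), rep(TRUE, 300))
  expect_true(all(f3$values[is.finite(f3$values)] == 1))
})

test_that("boxcar binning attenuates an injected cosine by 2/pi", {
  set.seed(77)
  n <- 10000
  phi <- runif(n, -pi, pi)
  p <- 0.5 + 0.2 * cos(phi - deg2rad(90))
  hit <- runif(n) < p
  ft <- one_cycle_sine_amplitude(phase_binned_hit_rate(phi, hit))
  expect_lt(abs(ft$amplitude - (2 / pi) * 0.2), 0.1 * (2 / pi) * 0.2)
  expect_lt(circ_diff_deg(ft$preferred_phase_deg, 90), 10)
})

test_that("pretarget phase obeys the cosine convention", {
  sig <- cosine_signal(5, n_trials = 2, t0_ms = -1500, stop_ms = 500)
  sp <- morlet_transform(sig, 5, n_cycles = 3, times_ms = c(-400, -350))
  # -400 ms is a 5 Hz cosine peak (period 200 ms)
  expect_lt(abs(pretarget_phase(sp, -400)[1, 1]), 0.05)
  # a quarter cycle later the phase has advanced by +pi/2
  expect_lt(abs(pretarget_phase(sp, -350)[1, 1] - pi / 2), 0.05)
  sp_full <- morlet_transform(sig, 5, n_cycles = 3)
  expect_error(pretarget_phase(sp_full, -1490), "edge")
})

test_that("phase-detection spectrum is null-calibrated and rotation invariant", {
  set.seed(42)
  n <- 300
  freqs <- c(5, 10, 15)
  ph <- matrix(runif(n * 3, -pi, pi), n)
  out <- runif(n) < 0.5
  pd <- phase_detection_spectrum(ph, out, freqs, n_perm = 300, seed = 2)
  expect_false(any(pd$holm_significant))
  # rotating all phases by a constant shifts the preferred phase only
  pd2 <- phase_detection_spectrum(wrap_pi(ph + deg2rad(30)), out, freqs,
                                  n_perm = 300, seed = 2)
  expect_equal(pd2$amplitude, pd$amplitude, tolerance = 1e-9)
  expect_lt(max(circ_diff_deg(pd2$preferred_phase_deg,
                              pd$preferred_phase_deg + 30)), 1e-6)
  expect_error(phase_detection_spectrum(ph[1:20, ], out[1:20], freqs),
               "50")
})

test_that("a deterministic phase-outcome rule hits the permutation floor", {
  set.seed(43)
  n <- 400
  phi <- runif(n, -pi, pi)
  hit <- abs(wrap_pi(phi - deg2rad(90))) < pi / 2
  pd <- phase_detection_spectrum(matrix(phi), hit, 5, n_perm = 1500, seed = 3)
  expect_equal(pd$p, 1 / 1501, tolerance = 1e-12)
})

test_that("theta bins are defined from the 5 Hz fit with wraparound", {
  ft <- structure(list(preferred_phase_deg = 90), class = "sine_fit")
  b <- define_theta_bins(ft)
  expect_equal(b$good_center_deg, 90)
  expect_equal(b$poor_center_deg, 270)
  ft2 <- structure(list(preferred_phase_deg = 350), class = "sine_fit")
  expect_equal(define_theta_bins(ft2)$poor_center_deg, 170)
  # trial assignment splits the circle into two half-cycles
  th <- deg2rad(c(90, 100, 271, 30, 180 + 90))
  expect_equal(as.character(assign_theta_bin(th, b)),
               c("good", "good", "poor", "good", "poor"))
})

test_that("nested modulation localizes to its theta half-cycle", {
  # 15 Hz behavioral modulation active only during the good theta phase
  tr <- generate_trials(task_config(n_trials = 4000, seed = 61))
  cfg <- signal_config(alpha_band = c(14.5, 15.5), alpha_amp = 6,
                       pac_depth = 0, theta_amp = 10, fractal_sd = 3,
                       noise_sd = 1, seed = 62)
  lfp <- synthesize_lfp(tr, cfg, t0_ms = -1500, stop_ms = 500)
  beh <- synthesize_behavior(tr, lfp, behavior_config(
    p0 = 0.5, theta_mod_depth = 0.1, good_phase_deg = 90,
    nested = list(depth = 0.5, active_bin = "good", good_phase_deg = 0),
    seed = 63))
  keep <- analyzable_trials(beh)
  lfp2 <- lfp
  lfp2$samples <- lfp$samples[keep, , drop = FALSE]
  lfp2$trial_ids <- lfp$trial_ids[keep]
  freqs <- seq(9, 21, by = 1)
  sp <- morlet_transform(lfp2, freqs, n_cycles = 4, times_ms = -250)
  ph <- pretarget_phase(sp, -250)
  th_sp <- morlet_transform(lfp2, 5, n_cycles = 2, times_ms = -250)
  theta_phase <- drop(Arg(th_sp$coef[[1]]))
  bins <- define_theta_bins(structure(list(preferred_phase_deg = 90),
                                      class = "sine_fit"))
  res <- theta_binned_phase_detection(ph, beh$outcome[keep], theta_phase,
                                      bins, freqs, n_perm = 1500, seed = 64)
  band <- freqs >= 13 & freqs <= 17
  expect_true(any(res$good$holm_significant[band]))
  expect_false(any(res$poor$holm_significant[band]))
})
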