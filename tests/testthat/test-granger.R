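test_that("preprocessing decimates and z-normalizes per trial", {
  set.seed(1)
  x <- matrix(rnorm(5 * 1000), 5)
  sig <- epoched_signal(x, 1000, -500, 1:5)
  ep <- preprocess_gc(list(a = sig, b = sig))
  expect_equal(dim(ep$data), c(5, 250, 2))
  expect_equal(ep$rate_hz, 250)
  mus <- apply(ep$data[, , 1], 1, mean)
  sds <- apply(ep$data[, , 1], 1, sd)
  expect_lt(max(abs(mus)), 1e-12)
  expect_equal(sds, rep(1, 5), tolerance = 1e-12)
  # constant (zero-variance) input is rejected
  flat <- epoched_signal(matrix(2, 5, 1000), 1000, -500, 1:5)
  expect_error(preprocess_gc(list(a = flat, b = sig)), "zero-variance")
})

test_that("MVAR fitting recovers known coefficients", {
  A <- array(0, c(2, 2, 2))
  A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.3; A[2, 1, 1] <- 0.4; A[1, 2, 2] <- -0.25
  cc <- coupling_config(var_coefficients = A, seed = 2)
  tr <- tiny_trials(200)
  sigs <- synthesize_coupled_regions(tr, cc, n_samples = 200)
  X <- array(c(sigs[[1]]$samples, sigs[[2]]$samples), c(200, 200, 2))
  m <- fit_mvar(X, order = 8, rate_hz = 250)
  expect_true(m$stable)
  expect_lt(max(abs(m$coefficients[, , 1:2] - A)), 0.05)
  expect_lt(max(abs(m$coefficients[, , 3:8])), 0.05)
  # noise covariance self-consistency (unit-variance innovations)
  expect_lt(max(abs(m$noise_cov - diag(2))), 0.05)
  # independent white channels: all cross-terms near zero
  set.seed(3)
  W <- array(rnorm(100 * 150 * 2), c(100, 150, 2))
  mw <- fit_mvar(W, order = 4, rate_hz = 250)
  expect_lt(max(abs(mw$coefficients[1, 2, ]), abs(mw$coefficients[2, 1, ])),
            0.05)
})

test_that("spectral GC matches the lagged-copy closed form", {
  X <- lagged_pair(200, 200, c_lag = 1, seed = 4)
  m <- fit_mvar(X, order = 8, rate_hz = 250)
  g <- spectral_granger(m, freqs = seq(0.5, 124.5, by = 0.5))
  # Geweke measure for Y_t = X_{t-1} + e is flat at ln 2
  expect_equal(mean(g$values[["1->2"]]), log(2), tolerance = 0.1 * log(2))
  expect_lt(max(g$values[["2->1"]]), 0.01)
  # diagonal VAR: no influence either way
  set.seed(5)
  W <- array(rnorm(100 * 200 * 2), c(100, 200, 2))
  gw <- spectral_granger(fit_mvar(W, order = 8, rate_hz = 250))
  expect_lt(max(unlist(gw$values)), 0.01)
})

test_that("oscillatory coupling produces a band-limited GC peak", {
  # X resonates at 14 Hz (at 250 Hz sampling) and feeds Y
  A <- array(0, c(2, 2, 2))
  r <- 0.9; f0 <- 14; fs <- 250
  A[1, 1, 1] <- 2 * r * cos(2 * pi * f0 / fs); A[1, 1, 2] <- -r^2
  A[2, 2, 1] <- 0.3; A[2, 1, 1] <- 0.8
  cc <- coupling_config(var_coefficients = A, seed = 6)
  tr <- tiny_trials(150)
  sigs <- synthesize_coupled_regions(tr, cc, n_samples = 250)
  X <- array(c(sigs[[1]]$samples, sigs[[2]]$samples), c(150, 250, 2))
  g <- spectral_granger(fit_mvar(X, order = 8, rate_hz = 250),
                        freqs = seq(3, 60, by = 0.5))
  f_peak <- g$freqs_hz[which.max(g$values[["1->2"]])]
  expect_lt(abs(f_peak - 14), 2)
})

test_that("conditional GC removes chain-mediated influence but keeps direct", {
  Xc <- chain_triple(200, 200, seed = 7)
  pair <- spectral_granger(fit_mvar(Xc[, , 1:2], order = 8, rate_hz = 250))
  expect_gt(max(pair$values[["1->2"]]), 0.1)
  cond <- conditional_granger(Xc, source = 1, sink = 2, conditioning = 3,
                              order = 8)
  expect_lt(max(cond$values[[1]]), 0.02)
  # direct influence with an irrelevant conditioning channel is unchanged
  set.seed(8)
  Xd <- array(rnorm(200 * 200 * 3), c(200, 200, 3))
  for (i in 1:200) Xd[i, , 2] <- c(0, Xd[i, -200, 1]) + rnorm(200)
  pd <- spectral_granger(fit_mvar(Xd[, , 1:2], order = 8, rate_hz = 250))
  cd <- conditional_granger(Xd, 1, 2, 3, order = 8)
  expect_equal(mean(cd$values[[1]]), mean(pd$values[["1->2"]]),
               tolerance = 0.1)
  # no coupling anywhere: conditional flat near zero
  set.seed(9)
  Xn <- array(rnorm(150 * 150 * 3), c(150, 150, 3))
  cn <- conditional_granger(Xn, 1, 2, 3, order = 8)
  expect_lt(max(cn$values[[1]]), 0.02)
})

test_that("theta-binned GC swaps exactly under bin relabeling", {
  tr <- generate_trials(task_config(n_trials = 200, seed = 10))
  cfg <- signal_config(theta_amp = 10, fractal_sd = 2, alpha_amp = 2,
                       noise_sd = 0.5, seed = 11)
  th_lfp <- synthesize_lfp(tr, cfg, t0_ms = -1500, stop_ms = 500)
  A <- array(0, c(2, 2, 1)); A[1, 1, 1] <- 0.4; A[2, 2, 1] <- 0.4
  cc <- coupling_config(var_coefficients = A, seed = 12)
  sigs <- synthesize_coupled_regions(tr, cc, n_samples = 250)
  ep <- structure(list(data = array(c(sigs[[1]]$samples, sigs[[2]]$samples),
                                    c(200, 250, 2)),
                       rate_hz = 250, t0_ms = -500), class = "gc_epochs")
  bins <- define_theta_bins(structure(list(preferred_phase_deg = 90),
                                      class = "sine_fit"))
  flipped <- define_theta_bins(structure(list(preferred_phase_deg = 270),
                                         class = "sine_fit"))
  a <- theta_binned_granger(ep, th_lfp, bins, order = 4)
  b <- theta_binned_granger(ep, th_lfp, flipped, order = 4)
  expect_equal(a$good$values, b$poor$values, tolerance = 1e-12)
  expect_equal(a$poor$values, b$good$values, tolerance = 1e-12)
})

test_that("the GC asymmetry permutation test detects one-way coupling", {
  X <- lagged_pair(100, 150, c_lag = 1, seed = 13)
  res <- gc_permutation_test(X, order = 8, freqs = seq(5, 55, by = 10),
                             n_perm = 300, seed = 14, rate_hz = 250)
  expect_true(any(res$holm_significant))
  expect_gt(mean(res$observed), 0.5)
  # symmetric coupling of equal strength: asymmetry not significant
  set.seed(15)
  Xs <- array(0, c(100, 150, 2))
  for (i in 1:100) {
    e1 <- rnorm(150); e2 <- rnorm(150)
    x <- e1; y <- e2
    for (t in 2:150) {
      x[t] <- 0.4 * y[t - 1] + e1[t]
      y[t] <- 0.4 * x[t - 1] + e2[t]
    }
    Xs[i, , 1] <- x; Xs[i, , 2] <- y
  }
  rs <- gc_permutation_test(Xs, order = 8, freqs = seq(5, 55, by = 10),
                            n_perm = 300, seed = 16, rate_hz = 250)
  expect_false(any(rs$holm_significant))
})
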