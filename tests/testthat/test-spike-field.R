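ppc_brute <- function(th) {
  n <- length(th)
  d <- outer(th, th, "-")
  mean(cos(d[lower.tri(d)]))
}

test_that("closed-form PPC equals the brute-force pairwise mean", {
  expect_equal(ppc(c(0.3, 0.3, 0.3)), 1, tolerance = 1e-12)
  expect_equal(ppc(c(0, pi)), -1, tolerance = 1e-12)
  expect_equal(ppc(c(0, pi / 2, pi, 3 * pi / 2)), -1 / 3, tolerance = 1e-12)
  expect_true(is.na(ppc(0.5)))
  set.seed(10)
  for (r in 1:100) {
    n <- sample(2:200, 1)
    th <- runif(n, -pi, pi)
    expect_equal(ppc(th), ppc_brute(th), tolerance = 1e-12)
  }
})

test_that("PPC expectation matches (I1/I0)^2 under von Mises sampling", {
  set.seed(11)
  for (kappa in c(0, 0.5, 1, 2)) {
    vals <- vapply(1:200, function(u) ppc(rvonmises(150, 0, kappa)),
                   numeric(1))
    expected <- if (kappa == 0) 0 else
      (besselI(kappa, 1) / besselI(kappa, 0))^2
    se <- sd(vals) / sqrt(200)
    expect_lt(abs(mean(vals) - expected), 3 * se)
  }
})

test_that("PPC is invariant to global rotation and dataset duplication", {
  set.seed(12)
  th <- rvonmises(80, 1, 1.5)
  expect_equal(ppc(th), ppc(wrap_pi(th + 1.1)), tolerance = 1e-12)
  # duplicating all phases moves PPC toward the same population value
  expect_equal(ppc(c(th, th)),
               (Mod(sum(exp(1i * th)) * 2)^2 - 160) / (160 * 159),
               tolerance = 1e-12)
})

test_that("spike phases are read off the LFP at spike times", {
  sig <- cosine_signal(10, n_trials = 2, t0_ms = -1000, stop_ms = 250)
  # spikes at 10 Hz cosine peaks within the analysis window
  peaks <- seq(-500, -200, by = 100)
  st <- spike_train(list(peaks, peaks + 50), 1:2)  # trial 2 at troughs
  sp <- morlet_transform(sig, 10, n_cycles = 3)
  ps <- extract_spike_phases(st, sp, c(-500, -125))
  ph1 <- ps$phases[ps$trial_index == 1, 1]
  ph2 <- ps$phases[ps$trial_index == 2, 1]
  expect_true(all(abs(ph1) < 0.1))
  expect_true(all(abs(abs(ph2) - pi) < 0.1))
  # no spikes in window -> flagged empty
  st0 <- spike_train(list(c(100, 200)), 1L)
  expect_true(extract_spike_phases(st0, sp, c(-500, -125))$empty)
})

test_that("condition PPC contrast is antisymmetric and detects true differences", {
  set.seed(13)
  mk_set <- function(kappa, n_trials = 60, spikes_per = 6, mu = 0) {
    ph <- rvonmises(n_trials * spikes_per, mu, kappa)
    structure(list(freqs_hz = 15,
                   phases = matrix(ph, ncol = 1),
                   trial_index = rep(seq_len(n_trials), each = spikes_per),
                   spike_times_ms = numeric(n_trials * spikes_per),
                   n_spikes = n_trials * spikes_per, empty = FALSE),
              class = "spike_phase_set")
  }
  cued <- mk_set(1.5); noncued <- mk_set(0)
  res <- condition_ppc_contrast(cued, noncued, n_perm = 500, seed = 14)
  expect_gt(res$delta, 0)
  expect_lt(res$p, 0.05)
  swapped <- condition_ppc_contrast(noncued, cued, n_perm = 500, seed = 14)
  expect_equal(swapped$delta, -res$delta, tolerance = 1e-12)
  # identical coupling: no rejection expected for this single draw
  same <- condition_ppc_contrast(mk_set(1), mk_set(1), n_perm = 500,
                                 seed = 15)
  expect_gt(same$p, 0.01)
  empty <- mk_set(1); empty$empty <- TRUE
  expect_error(condition_ppc_contrast(empty, noncued), "no spikes")
})

test_that("theta-dependent PPC is equivariant under theta rotation", {
  set.seed(16)
  n_sp <- 1500
  theta <- runif(n_sp, -pi, pi)
  gate <- abs(wrap_pi(theta - deg2rad(90))) <= pi / 2
  ph15 <- ifelse(gate, rvonmises(n_sp, 0, 2), runif(n_sp, -pi, pi))
  sps <- structure(list(freqs_hz = 15, phases = matrix(ph15, ncol = 1),
                        trial_index = rep(1L, n_sp),
                        spike_times_ms = numeric(n_sp),
                        n_spikes = n_sp, empty = FALSE),
                   class = "spike_phase_set")
  r1 <- theta_dependent_ppc(sps, theta, n_perm = 200, seed = 17)
  r2 <- theta_dependent_ppc(sps, wrap_pi(theta + deg2rad(30)),
                            n_perm = 200, seed = 17)
  expect_equal(r2$amplitude, r1$amplitude, tolerance = 1e-9)
  expect_lt(circ_diff_deg(r2$preferred_phase_deg,
                          r1$preferred_phase_deg + 30), 1)
  # the gated construction peaks near the gate center
  expect_lt(circ_diff_deg(r1$preferred_phase_deg, 90), 20)
  expect_lt(r1$p, 0.05)
})

test_that("theta-independent coupling yields no theta modulation", {
  set.seed(18)
  n_sp <- 1200
  theta <- runif(n_sp, -pi, pi)
  ph <- rvonmises(n_sp, 0, 1.5)   # coupled, but independent of theta
  sps <- structure(list(freqs_hz = 15, phases = matrix(ph, ncol = 1),
                        trial_index = rep(1L, n_sp),
                        spike_times_ms = numeric(n_sp),
                        n_spikes = n_sp, empty = FALSE),
                   class = "spike_phase_set")
  r <- theta_dependent_ppc(sps, theta, n_perm = 300, seed = 19)
  expect_gt(r$p, 0.05)
})

test_that("stratification removes power confounds but keeps true gating", {
  set.seed(20)
  n_sp <- 4000
  theta <- runif(n_sp, -pi, pi)
  in90 <- abs(wrap_pi(theta - deg2rad(90))) < pi / 2
  # power higher in the 90-degree half-cycle (PAC); phase reliability
  # increases with power -> spurious theta dependence
  power <- exp(rnorm(n_sp, mean = ifelse(in90, 1, 0), sd = 0.5))
  kappa_sp <- 1.5 * pmin(power, 2)
  ph_sp <- vapply(seq_len(n_sp), function(i) rvonmises(1, 0, kappa_sp[i]),
                  numeric(1))
  res_sp <- stratified_theta_ppc(ph_sp, theta, power, n_iter = 300,
                                 seed = 21)
  expect_lt(abs(res_sp$mean_diff), 3 * res_sp$sd_diff)
  # truly theta-gated coupling with the same power confound survives
  ph_true <- ifelse(in90, rvonmises(n_sp, 0, 2), runif(n_sp, -pi, pi))
  res_tr <- stratified_theta_ppc(ph_true, theta, power, n_iter = 300,
                                 seed = 22)
  expect_gt(res_tr$mean_diff, 3 * res_tr$sd_diff)
})
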