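test_that("transient kernel peaks at the closed-form time and at the requested amplitude", {
  kin <- kinetic_params(1, 0.010, 0.100)
  # closed-form peak time of the difference of exponentials
  tstar <- log(0.100 / 0.010) * 0.010 * 0.100 / (0.100 - 0.010)
  expect_equal(tstar, 0.02558428, tolerance = 1e-6)
  # fine-grid argmax agrees with the closed form
  k_fine <- make_transient_kernel(kin, dt = 1e-5)
  tt <- attr(k_fine, "times")
  expect_lt(abs(tt[which.max(k_fine)] - tstar), 2e-5)
  expect_equal(attr(k_fine, "peak_time"), tstar, tolerance = 1e-12)
  # sampled maximum equals the amplitude by construction, k(0) = 0
  k <- make_transient_kernel(kin, dt = 0.004)
  expect_equal(max(k), 1, tolerance = 1e-9)
  expect_identical(k[1L], 0)
  k2 <- make_transient_kernel(kinetic_params(1, 0.001, 0.100), dt = 0.004)
  expect_equal(max(k2), 1, tolerance = 1e-9)
})

test_that("degenerate kernel inputs are rejected and zero amplitude yields a flat kernel", {
  expect_error(kinetic_params(1, 0.1, 0.1), "tau_rise < tau_decay")
  expect_error(make_transient_kernel(kinetic_params(1, 0.01, 0.1), dt = 0),
               "dt")
  expect_error(make_transient_kernel(kinetic_params(1, 0.01, 0.1),
                                     dt = 0.004, duration = 0.2),
               "duration")
  k0 <- make_transient_kernel(kinetic_params(0, 0.01, 0.1), dt = 0.004)
  expect_true(all(k0 == 0))
})

test_that("depletion recursion reproduces the oracle and its frequency ordering", {
  # no depression: every relative amplitude is 1
  expect_equal(depletion_amplitudes(60, 1, depletion_params(0, 5)),
               rep(1, 60))
  # generator matches an independent statement of the recursion
  for (u in c(0.1, 0.2, 0.5)) for (isi in c(0.25, 0.5, 1)) {
    expect_equal(depletion_amplitudes(60, isi, depletion_params(u, 5)),
                 oracle_depletion(60, isi, u, 5), tolerance = 1e-12)
  }
  # steady state at 4 Hz strictly below 1 Hz for u = 0.2, tau_rec = 5 s
  a1 <- depletion_amplitudes(60, 1, depletion_params(0.2, 5))
  a4 <- depletion_amplitudes(60, 0.25, depletion_params(0.2, 5))
  expect_lt(a4[60], a1[60])
  # monotone non-increasing steady state in frequency
  finals <- vapply(c(1, 2, 4), function(f)
    depletion_amplitudes(60, 1 / f, depletion_params(0.2, 5))[60],
    numeric(1L))
  expect_true(all(diff(finals) < 0))
  # floor clips the amplitudes
  af <- depletion_amplitudes(60, 0.25, depletion_params(0.5, 5, floor = 0.3))
  expect_true(all(af >= 0.3))
})

test_that("simulated sessions are bit-reproducible and carry exact ground truth", {
  prot <- stimulus_protocol(10, frequency = 2)
  args <- list(prot, kinetic_params(0.8, 0.01, 0.1),
               depletion_params(0.2, 5),
               noise_params(gaussian_sd = 0.03, spontaneous_rate = 4,
                            drift_amplitude = 0.02))
  s1 <- do.call(simulate_session, c(args, seed = 7))
  s2 <- do.call(simulate_session, c(args, seed = 7))
  s3 <- do.call(simulate_session, c(args, seed = 8))
  expect_identical(s1$recording$values, s2$recording$values)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$recording$values, s3$recording$values))
  # noise-free, depression-free session at 1 Hz (transients fully decay
  # between stimuli): all stimulus-locked peaks equal
  s0 <- simulate_session(stimulus_protocol(10, frequency = 1),
                         kinetic_params(0.8, 0.01, 0.1),
                         depletion_params(0, 5),
                         noise_params(gaussian_sd = 0), seed = 1)
  pk <- stimulus_locked_peaks(s0$recording, window = 0.4)
  expect_equal(pk, rep(0.8, 10), tolerance = 1e-9)
  expect_error(simulate_session(stimulus_protocol(5, frequency = 200),
                                kinetic_params(), seed = 1),
               "ISI")
})

test_that("spontaneous event counts are Poisson with the requested mean", {
  counts <- vapply(1:1000, function(seed) {
    s <- simulate_session(stimulus_protocol(1, frequency = 1),
                          kinetic_params(0, 0.01, 0.1),
                          noise = noise_params(gaussian_sd = 0,
                                               spontaneous_rate = 4),
                          seed = seed, pre_s = 2, post_s = 58)
    length(s$truth$spontaneous_onsets)
  }, numeric(1L))
  expect_lt(abs(mean(counts) - 4), 0.2)
  # chi-square goodness of fit against Poisson(4), alpha = 0.01
  brk <- c(-Inf, 1:8, Inf)
  obs <- table(cut(counts, brk))
  p_exp <- diff(stats::ppois(c(-1, 1:8, Inf), 4))
  gof <- stats::chisq.test(as.numeric(obs), p = p_exp)
  expect_gt(gof$p.value, 0.01)
})

test_that("behavioural cohorts follow the exponential habituation law", {
  prot <- stimulus_protocol(60, frequency = 1)
  # no habituation limit: every trial is a response
  b_inf <- simulate_behavioral_cohort(10, prot, habituation_rate_k = Inf,
                                      p_floor = 0, seed = 1)
  expect_true(all(b_inf$responded == 1L))
  # mean observed probability at trial 10 near exp(-1) for k = 10
  b <- simulate_behavioral_cohort(70, prot, habituation_rate_k = 10,
                                  p_floor = 0, seed = 2)
  p10 <- mean(b$responded[b$trial_index == 10L])
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 70)
  expect_lt(abs(p10 - exp(-1)), 3 * se)
  # responder latencies: short-latency component inside the 2-12 ms window
  lat <- b$latency_ms[b$responded == 1L]
  expect_true(all(!is.na(lat)))
  expect_true(all(is.na(b$latency_ms[b$responded == 0L])))
  expect_true(all(lat >= 2))
  # amplitude-gated mode: uniform amplitudes and a 0.6 threshold give ~40%
  amp <- matrix(runif(70 * 60, 1e-6, 1), 70, 60)
  amp[1L, 1L] <- 1  # pin the maximum
  bg <- simulate_behavioral_cohort(70, prot, amplitudes = amp,
                                   escape_threshold_fraction = 0.6, seed = 3)
  rate <- mean(bg$responded)
  expect_lt(abs(rate - 0.4), 3 * sqrt(0.4 * 0.6 / (70 * 60)))
  expect_error(simulate_behavioral_cohort(0, prot), "empty")
  expect_error(simulate_behavioral_cohort(5, prot, p_floor = 1.5), "p_floor")
})

test_that("synthetic Z-stack frames register to their generating planes", {
  zz <- simulate_zstack_frames(30, drift_sequence = c(15, 15, 15),
                               noise_sd_frac = 0, seed = 1)
  planes <- vapply(zz$frames, function(f)
    select_z_plane(zz$stack, f)$plane, integer(1L))
  expect_identical(planes, rep(15L, 3L))
  expect_error(simulate_zstack_frames(30, drift_sequence = c(10, 31)),
               "drift index")
  z1 <- simulate_zstack_frames(1, drift_sequence = 1, noise_sd_frac = 0.05,
                               seed = 2)
  expect_identical(select_z_plane(z1$stack, z1$frames[[1L]])$plane, 1L)
})
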