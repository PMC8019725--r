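test_that("stimulus-locked peaks track the depletion recursion", {
  s <- simulate_session(stimulus_protocol(60, frequency = 1),
                        kinetic_params(0.8, 0.01, 0.1),
                        depletion_params(0.2, 5),
                        noise_params(gaussian_sd = 0), seed = 31)
  pk <- stimulus_locked_peaks(s$recording)
  oracle <- 0.8 * oracle_depletion(60, 1, 0.2, 5)
  expect_equal(pk, oracle, tolerance = 1e-6)
  # window wider than the ISI and out-of-range onsets are rejected
  expect_error(stimulus_locked_peaks(s$recording, window = 1.5),
               "ISI")
  expect_error(stimulus_locked_peaks(s$recording,
                                     onsets = max(s$recording$times) - 0.1),
               "trace end")
})

test_that("intensity curves normalize per fish to the reference volume", {
  ladder <- c(81.8, 83.8, 85.8, 89.8, 91.7)
  peaks <- expand.grid(fish_id = 1:6, rep = 1:5, intensity_db = ladder)
  peaks$peak <- 0.2 + 0.8 / (1 + exp(-(peaks$intensity_db - 88) / 1.5))
  # per-fish gain must cancel exactly
  peaks$peak <- peaks$peak * peaks$fish_id
  curve <- build_intensity_curve(peaks, reference_db = 91.7)
  expect_equal(curve$normalized_mean[curve$intensity_db == 91.7], 1,
               tolerance = 1e-12)
  expect_true(all(curve$sd < 1e-12))  # gain washed out: no cohort spread
  expect_equal(nrow(curve), 5L)
  # all intensities at the reference level: constant 1.0
  flat <- peaks; flat$peak <- 3
  cf <- build_intensity_curve(flat)
  expect_equal(cf$normalized_mean, rep(1, 5), tolerance = 1e-12)
  expect_error(build_intensity_curve(peaks, reference_db = 95), "reference")
  # a fish with a zero reference response is excluded with a warning
  bad <- peaks
  bad$peak[bad$fish_id == 3 & bad$intensity_db == 91.7] <- 0
  expect_warning(cb <- build_intensity_curve(bad), "excluding fish")
  expect_equal(unique(cb$n_fish), 5)
})

test_that("depression curves are exactly 1 in bin 1 and gain-invariant", {
  # constant peaks: every bin is 1
  const <- matrix(0.7, nrow = 4, ncol = 60)
  dc <- depression_curve(const)
  expect_equal(dc$normalized_mean, rep(1, 12), tolerance = 1e-12)
  # depleting peaks: bin 1 exactly 1 for every fish, curve matches recursion
  rel <- oracle_depletion(60, 0.25, 0.2, 5)
  pk <- rbind(0.8 * rel, 1.3 * rel, 0.2 * rel)
  dc2 <- depression_curve(pk, frequency = 4)
  per_fish <- attr(dc2, "per_fish")
  expect_true(all(per_fish[, 1L] == 1))
  expect_equal(dc2$normalized_mean,
               as.numeric(bin_by_factor(rel, 5) / mean(rel[1:5])),
               tolerance = 1e-12)
  expect_equal(dc2$sd, rep(0, 12), tolerance = 1e-12)  # gain invariance
  expect_error(depression_curve(matrix(1, 2, 3), bin_k = 5), "fewer peaks")
  expect_error(depression_curve(matrix(1, 2, 13), bin_k = 5), "divisible")
})

test_that("depression deepens with stimulation frequency in simulated cohorts", {
  final_bin <- function(freq, seed) {
    pk <- t(vapply(1:10, function(f) {
      s <- simulate_session(stimulus_protocol(60, frequency = freq),
                            kinetic_params(0.8, 0.01, 0.1),
                            depletion_params(0.2, 5),
                            noise_params(gaussian_sd = 0.04),
                            seed = seed * 1000 + f)
      stimulus_locked_peaks(s$recording, window = min(1 / freq, 0.5))
    }, numeric(60L)))
    depression_curve(pk, frequency = freq)$normalized_mean[12L]
  }
  f1 <- final_bin(1, 1); f2 <- final_bin(2, 2); f4 <- final_bin(4, 3)
  expect_gt(f1, f2)
  expect_gt(f2, f4)
})

test_that("activation probability counts supra-threshold trials", {
  base <- sin(1:200) * 0.01  # baseline with variance
  hot <- list(baseline = base, post = c(rep(0, 50), 0.5, rep(0, 49)))
  cold <- list(baseline = base, post = rep(0, 100))
  p <- activation_probability(list(hot, hot, hot, cold, cold))
  expect_equal(as.numeric(p), 0.6)  # 3 of 5 trials
  expect_equal(as.numeric(activation_probability(list(cold, cold))), 0)
  flat <- list(baseline = rep(1, 100), post = rep(1, 100))
  expect_error(activation_probability(list(flat)), "zero-variance")
  # recovery of a true 0.6 activation probability, 13 fish x 5 trials
  set.seed(77)
  trials <- lapply(seq_len(13 * 5), function(i) {
    active <- runif(1) < 0.6
    # inactive trials stay well below threshold; active ones carry a
    # transient far above it
    list(baseline = rnorm(100, sd = 0.01),
         post = rnorm(100, sd = 0.002) + if (active) 0.3 else 0)
  })
  est <- as.numeric(activation_probability(trials))
  expect_lt(abs(est - 0.6), 3 * sqrt(0.6 * 0.4 / 65))
})

test_that("release-threshold estimation matches the exhaustive-scan oracle", {
  # perfectly separable data: threshold inside the straddling gap
  set.seed(7)
  amp <- runif(200, 0.01, 1); amp[1L] <- 1
  esc <- as.integer(amp > 0.6)
  r <- estimate_release_threshold(amp, esc)
  below <- max(amp[amp <= 0.6]); above <- min(amp[amp > 0.6])
  expect_gt(r$threshold, below)
  expect_lt(r$threshold, above)
  expect_equal(r$accuracy, 1)
  expect_true(r$informative)
  # oracle equivalence: dense grid scan never beats the returned accuracy
  for (seed in 1:5) {
    set.seed(seed)
    a <- runif(60); a[1L] <- 1
    e <- as.integer((a > 0.6) != (runif(60) < 0.1))  # 10% label noise
    rr <- estimate_release_threshold(a, e)
    grid_acc <- max(vapply(seq(0, 1, by = 1e-4), function(cut)
      mean((a > cut) == (e == 1L)), numeric(1L)))
    expect_equal(rr$accuracy, grid_acc, tolerance = 1e-9)
  }
  # escapes independent of amplitude: near base-rate accuracy, uninformative
  set.seed(8)
  a2 <- runif(200); e2 <- rbinom(200, 1, 0.5)
  r2 <- estimate_release_threshold(a2, e2)
  expect_false(r2$informative)
  # a single escape at the maximal amplitude: threshold just below 1
  a3 <- c(seq(0.1, 0.9, length.out = 20), 1)
  e3 <- c(rep(0L, 20), 1L)
  r3 <- estimate_release_threshold(a3, e3)
  expect_gt(r3$threshold, 0.9)
  expect_lt(r3$threshold, 1)
  expect_error(estimate_release_threshold(a3, rep(1L, 21)), "both escape")
  # logistic alternative lands near the same cut on separable-ish data
  r4 <- estimate_release_threshold(amp, esc, method = "logistic")
  expect_lt(abs(r4$threshold - 0.6), 0.05)
})

test_that("exponential habituation fits recover noiseless parameters exactly", {
  n <- 1:60
  p <- 0.1 + 0.9 * exp(-n / 10)
  fit <- fit_exponential_habituation(p)
  expect_lt(abs(fit$k - 10), 1e-6)
  expect_lt(abs(fit$p_floor - 0.1), 1e-6)
  expect_false(fit$poor_fit)
  # constant series: flagged as no habituation
  f1 <- fit_exponential_habituation(rep(1, 60))
  expect_true(f1$no_habituation)
  expect_error(fit_exponential_habituation(c(0.5, 0.4)), ">= 10 trials")
  expect_error(fit_exponential_habituation(rep(1.5, 20)), "\\[0, 1\\]")
})

test_that("habituation rate is recovered from Bernoulli cohorts", {
  prot <- stimulus_protocol(60, frequency = 1)
  ks <- vapply(1:10, function(seed) {
    beh <- simulate_behavioral_cohort(70, prot, habituation_rate_k = 10,
                                      p_floor = 0.1, seed = seed)
    ser <- habituation_probability_series(beh)
    fit_exponential_habituation(ser$probability, ser$trial_index)$k
  }, numeric(1L))
  expect_gte(mean(abs(ks - 10) / 10 <= 0.2), 0.9)
})
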