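# shared fixtures, built in code

# noise-free single-transient session; returns the dF/F0 vector, its times,
# and the (grid-snapped) event onset index
single_transient <- function(amplitude = 1, tau_rise = 0.010,
                             tau_decay = 0.100, noise_sd = 0, seed = 1,
                             sampling_rate = 250, pre_s = 0.2, post_s = 1) {
  s <- simulate_session(stimulus_protocol(1, frequency = 1),
                        kinetic_params(amplitude, tau_rise, tau_decay),
                        noise = noise_params(gaussian_sd = noise_sd),
                        sampling_rate = sampling_rate, seed = seed,
                        pre_s = pre_s, post_s = post_s)
  v <- as.numeric(s$recording$values[, 1L])
  onset_idx <- floor(s$truth$stimulus_onsets[1L] * sampling_rate) + 1L
  list(values = v, times = s$recording$times, onset_idx = onset_idx,
       session = s)
}

# independent re-statement of the depletion recursion, used as the oracle
# against the generator and the stimulus-locked analysis
oracle_depletion <- function(n, isi, u, tau_rec, floor = 0) {
  r <- 1; out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- max(floor, r)
    r <- r * (1 - u)
    if (i < n) r <- 1 - (1 - r) * exp(-isi / tau_rec)
  }
  out
}
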