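# Synthetic imaging and behavioural data with known ground truth, used to
# validate every analysis stage by parameter recovery.

# run expr with a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# analytic peak time of exp(-t/td) - exp(-t/tr), tr < td
kernel_peak_time <- function(tau_rise, tau_decay) {
  log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
}

#' Difference-of-exponentials transient kernel
#'
#' Evaluates the canonical indicator-transient waveform
#' `k(t) = A * c * (exp(-t / tau_decay) - exp(-t / tau_rise))` on a uniform
#' grid, with the normaliser `c` chosen so that `max(k) = amplitude` exactly
#' on the sampled grid. The continuous waveform peaks at
#' `t* = log(tau_decay/tau_rise) * tau_rise*tau_decay / (tau_decay -
#' tau_rise)`, returned in attribute `"peak_time"`. `k(0) = 0`.
#'
#' @param kinetics A [kinetic_params()] object.
#' @param dt Sample interval in seconds (> 0).
#' @param duration Kernel duration in seconds; must cover at least
#'   `5 * tau_decay` so the transient decays essentially to zero.
#' @return Numeric vector of dF/F0 values at `t = 0, dt, 2*dt, ...`, with the
#'   grid in attribute `"times"` and the analytic peak time in `"peak_time"`.
#' @examples
#' k <- make_transient_kernel(kinetic_params(1, 0.01, 0.1), dt = 0.004)
#' max(k) <= 1
#' @export
make_transient_kernel <- function(kinetics, dt,
                                  duration = 5 * kinetics$tau_decay) {
  stopifnot(inherits(kinetics, "kinetic_params"))
  if (dt <= 0) stop("make_transient_kernel: dt must be > 0")
  if (kinetics$tau_rise >= kinetics$tau_decay)
    stop("make_transient_kernel: degenerate waveform (tau_rise >= tau_decay)")
  if (duration < 5 * kinetics$tau_decay)
    stop("make_transient_kernel: duration must cover >= 5 * tau_decay")
  tt <- seq(0, duration, by = dt)
  tr <- kinetics$tau_rise; td <- kinetics$tau_decay
  tstar <- kernel_peak_time(tr, td)
  raw <- exp(-tt / td) - exp(-tt / tr)
  peak <- max(raw)
  k <- if (kinetics$amplitude == 0 || peak <= 0) raw * 0
    else kinetics$amplitude * raw / peak
  attr(k, "times") <- tt
  attr(k, "peak_time") <- tstar
  k
}

#' Relative release amplitudes under resource depletion
#'
#' Iterates the single-pool depletion recursion: the available resource `R`
#' starts at 1; each stimulus releases `u * R` (so the relative amplitude of
#' stimulus n is `R_n`, floored at `floor`), after which `R <- R * (1 - u)`;
#' between stimuli `R` recovers towards 1 as
#' `R <- 1 - (1 - R) * exp(-isi / tau_recovery)`.
#'
#' @param n_stimuli Number of stimuli.
#' @param isi Interstimulus interval in seconds.
#' @param depletion A [depletion_params()] object.
#' @return Numeric vector of `n_stimuli` relative amplitudes; the first is 1.
#' @examples
#' depletion_amplitudes(5, 1, depletion_params(0.2, 5))
#' @export
depletion_amplitudes <- function(n_stimuli, isi, depletion) {
  stopifnot(inherits(depletion, "depletion_params"))
  u <- depletion$release_fraction_u
  r <- 1
  amps <- numeric(n_stimuli)
  for (i in seq_len(n_stimuli)) {
    amps[i] <- max(depletion$floor, r)
    r <- r * (1 - u)
    if (i < n_stimuli)
      r <- 1 - (1 - r) * exp(-isi / depletion$tau_recovery)
  }
  amps
}

#' Simulate a stimulus-locked line-scan session
#'
#' Generates a fluorescence recording containing stimulus-locked transients
#' whose relative amplitudes follow the resource-depletion recursion
#' ([depletion_amplitudes()]), plus Poisson spontaneous release events,
#' additive Gaussian noise and a slow sinusoidal baseline drift. Ground truth
#' (event onsets and amplitudes) is returned alongside for recovery tests.
#'
#' @param protocol A [stimulus_protocol()].
#' @param kinetics A [kinetic_params()].
#' @param depletion A [depletion_params()]; `release_fraction_u = 0` disables
#'   depression.
#' @param noise A [noise_params()].
#' @param sampling_rate Hz; 250 for glutamate, 20 for calcium line scans.
#' @param seed Integer seed; the session is bit-reproducible given it.
#' @param pre_s Baseline duration before the first stimulus (seconds).
#' @param post_s Recording tail after the last stimulus (seconds).
#' @param amplitude_cv Lognormal coefficient of variation of per-event
#'   amplitudes (0 = deterministic amplitudes).
#' @param f0 Baseline fluorescence used when `emit = "raw"`.
#' @param emit `"dff"` to return dF/F0 directly, `"raw"` for
#'   `f0 * (1 + dff)` raw fluorescence.
#' @param evoked If `FALSE`, stimulus-locked transients are omitted (a
#'   passive recording of spontaneous release only); the stimulus onsets are
#'   still recorded as metadata.
#' @param roi_label,condition Labels stored on the recording.
#' @return A list with elements `recording` (a [trace_recording()]) and
#'   `truth` (list: `stimulus_onsets`, `relative_amplitudes`,
#'   `event_onsets`, `event_amplitudes`, `spontaneous_onsets`).
#' @examples
#' s <- simulate_session(stimulus_protocol(10, frequency = 1),
#'                       kinetic_params(), depletion_params(),
#'                       noise_params(), seed = 1)
#' s$recording
#' @export
simulate_session <- function(protocol, kinetics,
                             depletion = depletion_params(0, 5),
                             noise = noise_params(),
                             sampling_rate = 250, seed = 1,
                             pre_s = 2, post_s = 1, amplitude_cv = 0,
                             f0 = 100, emit = c("dff", "raw"),
                             evoked = TRUE,
                             roi_label = "AIS", condition = "vehicle") {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(kinetics, "kinetic_params"),
            inherits(depletion, "depletion_params"),
            inherits(noise, "noise_params"))
  emit <- match.arg(emit)
  dt <- 1 / sampling_rate
  if (protocol$isi < 2 * dt)
    stop("simulate_session: ISI shorter than two sample intervals")
  with_seed(seed, {
    n_samp <- ceiling((pre_s + (protocol$n_stimuli - 1) * protocol$isi +
                         post_s) * sampling_rate) + 1L
    times <- (seq_len(n_samp) - 1L) * dt
    duration <- times[n_samp]
    onsets <- pre_s + (seq_len(protocol$n_stimuli) - 1L) * protocol$isi
    if (kinetics$onset_jitter_sd > 0)
      onsets <- onsets + stats::rnorm(length(onsets),
                                      sd = kinetics$onset_jitter_sd)
    rel <- depletion_amplitudes(protocol$n_stimuli, protocol$isi, depletion)
    amps <- kinetics$amplitude * rel
    n_spont <- stats::rpois(1L, noise$spontaneous_rate / 60 * duration)
    spont_onsets <- sort(stats::runif(n_spont, 0, duration))
    spont_amps <- rep(kinetics$amplitude, n_spont)
    if (amplitude_cv > 0) {
      sdl <- sqrt(log(1 + amplitude_cv^2))
      scale_ev <- function(a)
        a * stats::rlnorm(length(a), meanlog = -sdl^2 / 2, sdlog = sdl)
      amps <- scale_ev(amps)
      spont_amps <- scale_ev(spont_amps)
    }
    ev_onsets <- if (evoked) c(onsets, spont_onsets) else spont_onsets
    ev_amps <- if (evoked) c(amps, spont_amps) else spont_amps
    sig <- numeric(n_samp)
    if (kinetics$amplitude > 0 && length(ev_onsets)) {
      kern <- make_transient_kernel(
        kinetic_params(1, kinetics$tau_rise, kinetics$tau_decay), dt,
        duration = max(5, 7) * kinetics$tau_decay)
      nk <- length(kern)
      for (j in seq_along(ev_onsets)) {
        i0 <- floor(ev_onsets[j] / dt) + 1L
        idx <- i0:min(i0 + nk - 1L, n_samp)
        if (i0 <= n_samp)
          sig[idx] <- sig[idx] + ev_amps[j] * kern[seq_along(idx)]
      }
    }
    if (noise$drift_amplitude != 0)
      sig <- sig + noise$drift_amplitude *
        sin(2 * pi * times / noise$drift_period)
    if (noise$gaussian_sd > 0)
      sig <- sig + stats::rnorm(n_samp, sd = noise$gaussian_sd)
    vals <- if (emit == "raw") f0 * (1 + sig) else sig
    rec <- trace_recording(times, vals, sampling_rate,
                           roi_label = roi_label,
                           stimulus_onsets = onsets, condition = condition,
                           units = if (emit == "raw") "raw" else "dff")
    list(recording = rec,
         truth = list(stimulus_onsets = onsets, relative_amplitudes = rel,
                      event_onsets = ev_onsets, event_amplitudes = ev_amps,
                      spontaneous_onsets = spont_onsets))
  })
}

#' Simulate a reference Z-stack and drifted single frames
#'
#' Builds a smooth synthetic 3-D intensity object — two Gaussian blobs whose
#' in-plane centres travel along z, so neighbouring slices decorrelate
#' quickly and every slice is distinguishable — slices it into a reference
#' stack, and records one noisy single frame per stimulus at the requested
#' (drifted) focal planes: the input expected by [select_z_plane()].
#'
#' @param n_slices Number of slices in the reference stack (default 30).
#' @param increment Slice spacing in micrometres (default 2).
#' @param drift_sequence Integer plane indices (1-based) at which single
#'   frames are acquired; all must lie in `[1, n_slices]`.
#' @param dim In-plane frame dimensions in pixels.
#' @param noise_sd_frac Frame noise SD as a fraction of the stack's peak
#'   intensity.
#' @param seed Integer seed.
#' @return A list with `stack` (a [zstack()]) and `frames` (list of noisy
#'   matrices, one per entry of `drift_sequence`).
#' @export
simulate_zstack_frames <- function(n_slices = 30, increment = 2,
                                   drift_sequence = integer(),
                                   dim = c(32, 32), noise_sd_frac = 0.05,
                                   seed = 1) {
  if (n_slices < 1) stop("simulate_zstack_frames: n_slices must be >= 1")
  drift_sequence <- as.integer(drift_sequence)
  if (length(drift_sequence) &&
      (min(drift_sequence) < 1L || max(drift_sequence) > n_slices))
    stop("simulate_zstack_frames: drift index outside [1, n_slices]")
  x <- seq_len(dim[1L]); y <- seq_len(dim[2L])
  frac <- if (n_slices == 1L) 0.5 else
    (seq_len(n_slices) - 1L) / (n_slices - 1L)
  sx <- dim[1L] / 14; sy <- dim[2L] / 14
  blob_slice <- function(cx, cy, s1, s2, w)
    w * outer(exp(-(x - cx)^2 / (2 * s1^2)), exp(-(y - cy)^2 / (2 * s2^2)))
  # two blobs whose centres travel along different axes with z, so the
  # in-plane pattern changes quickly and asymmetrically along z
  slices <- lapply(seq_len(n_slices), function(i) {
    f <- frac[i]
    blob_slice(dim[1L] * (0.15 + 0.7 * f), dim[2L] * 0.35,
               sx, sy * 1.2, 1.0) +
      blob_slice(dim[1L] * 0.65, dim[2L] * (0.15 + 0.7 * f),
                 sx * 1.2, sy, 0.8)
  })
  peak <- max(vapply(slices, max, numeric(1L)))
  stack <- zstack(slices, increment = increment)
  frames <- with_seed(seed, lapply(drift_sequence, function(p) {
    slices[[p]] + matrix(stats::rnorm(prod(dim), sd = noise_sd_frac * peak),
                         dim[1L], dim[2L])
  }))
  list(stack = stack, frames = frames)
}

#' Simulate a line-scan space-by-time matrix with imposed X-Y drift
#'
#' A fixed spatial fluorescence profile (Gaussian bump across the scan line)
#' observed repeatedly over time, shifted along the line by a known integer
#' number of samples at each time point, with additive noise — the input
#' expected by [correct_xy_drift()].
#'
#' @param n_pixels Samples along the scan line.
#' @param n_time Number of time points (columns).
#' @param shift_sequence Integer shift per time point (length `n_time` or a
#'   scalar; positive = profile moves towards higher indices).
#' @param noise_sd Additive Gaussian noise SD relative to the unit-peak
#'   profile.
#' @param seed Integer seed.
#' @return A list with `matrix` (`n_pixels` x `n_time`), `profile` (the
#'   un-shifted spatial profile) and `shifts` (the imposed integer shifts).
#' @export
simulate_linescan_matrix <- function(n_pixels = 64, n_time = 300,
                                     shift_sequence = 0, noise_sd = 0,
                                     seed = 1) {
  shifts <- as.integer(rep_len(shift_sequence, n_time))
  xx <- seq_len(n_pixels)
  profile <- exp(-(xx - n_pixels / 2)^2 / (2 * (n_pixels / 10)^2)) +
    0.3 * exp(-(xx - n_pixels / 4)^2 / (2 * (n_pixels / 20)^2))
  m <- with_seed(seed, {
    cols <- vapply(shifts, function(s) shift_profile(profile, s),
                   numeric(n_pixels))
    if (noise_sd > 0)
      cols <- cols + matrix(stats::rnorm(length(cols), sd = noise_sd),
                            nrow = n_pixels)
    cols
  })
  list(matrix = m, profile = profile, shifts = shifts)
}

# shift a profile by s samples (positive -> towards higher indices),
# replicating edge values
shift_profile <- function(p, s) {
  n <- length(p)
  if (s == 0) return(p)
  if (s > 0) c(rep(p[1L], min(s, n)), p[seq_len(max(n - s, 0L))])
  else c(p[(-s + 1L):n], rep(p[n], min(-s, n)))
}

#' Simulate a behavioural startle-habituation cohort
#'
#' Generates one trial table per fish x stimulus. By default the response is
#' Bernoulli with probability `p(n) = p_floor + (1 - p_floor) * exp(-n / k)`
#' at trial n (exponential habituation towards a floor). When per-trial
#' release `amplitudes` are supplied, the response is instead deterministic:
#' escape iff the amplitude exceeds `escape_threshold_fraction` of the maximal
#' supplied amplitude. Responders receive a latency drawn from a truncated
#' normal inside the short-latency window (2-12 ms), with a configurable
#' long-latency mixture component for the rare non-Mauthner escapes.
#'
#' @param n_fish Number of fish (>= 1).
#' @param protocol A [stimulus_protocol()]; supplies trial count, frequency
#'   and intensities.
#' @param habituation_rate_k Habituation rate constant in trials (> 0;
#'   `Inf` = no habituation).
#' @param p_floor Asymptotic response probability in `[0, 1]`.
#' @param latency_mean,latency_sd Mean and SD (ms) of the short-latency
#'   component.
#' @param slc_window Inclusive short-latency window in ms (default `c(2, 12)`).
#' @param long_latency_prob Probability that a response is long-latency.
#' @param long_latency_mean,long_latency_sd Long-latency component (ms),
#'   truncated above the window.
#' @param amplitudes Optional release amplitudes: a vector of length
#'   `n_stimuli` (shared across fish) or an `n_fish x n_stimuli` matrix.
#' @param escape_threshold_fraction Threshold as a fraction of the maximal
#'   amplitude, in `[0, 1]`.
#' @param condition Condition label for all trials.
#' @param seed Integer seed.
#' @return A data.frame of behaviour trials: `fish_id`, `trial_index`,
#'   `intensity_db`, `frequency_hz`, `responded` (0/1), `latency_ms` (NA for
#'   non-responders), `direction` (`left`/`right`/`absent`), `condition`.
#' @export
simulate_behavioral_cohort <- function(n_fish, protocol,
                                       habituation_rate_k = 10,
                                       p_floor = 0.1,
                                       latency_mean = 6, latency_sd = 2,
                                       slc_window = c(2, 12),
                                       long_latency_prob = 0.05,
                                       long_latency_mean = 20,
                                       long_latency_sd = 5,
                                       amplitudes = NULL,
                                       escape_threshold_fraction = 0.6,
                                       condition = "vehicle", seed = 1) {
  if (n_fish < 1) stop("simulate_behavioral_cohort: empty cohort")
  if (p_floor < 0 || p_floor > 1)
    stop("simulate_behavioral_cohort: p_floor must lie in [0, 1]")
  if (!is.infinite(habituation_rate_k) && habituation_rate_k <= 0)
    stop("simulate_behavioral_cohort: habituation_rate_k must be > 0")
  if (escape_threshold_fraction < 0 || escape_threshold_fraction > 1)
    stop("simulate_behavioral_cohort: escape_threshold_fraction in [0, 1]")
  n_tr <- protocol$n_stimuli
  if (!is.null(amplitudes)) {
    amplitudes <- if (is.matrix(amplitudes)) amplitudes
      else matrix(amplitudes, n_fish, n_tr, byrow = TRUE)
    if (!all(dim(amplitudes) == c(n_fish, n_tr)))
      stop("simulate_behavioral_cohort: amplitudes must be n_fish x n_stimuli")
  }
  rtrunc <- function(n, mean, sd, lo, hi) {
    out <- numeric(n)
    need <- seq_len(n)
    while (length(need)) {
      draw <- stats::rnorm(length(need), mean, sd)
      ok <- draw >= lo & draw <= hi
      out[need[ok]] <- draw[ok]
      need <- need[!ok]
    }
    out
  }
  with_seed(seed, {
    grid <- expand.grid(trial_index = seq_len(n_tr),
                        fish_id = seq_len(n_fish))
    n <- nrow(grid)
    if (is.null(amplitudes)) {
      p <- p_floor + (1 - p_floor) * exp(-grid$trial_index / habituation_rate_k)
      responded <- stats::rbinom(n, 1L, p)
    } else {
      thr <- escape_threshold_fraction * max(amplitudes)
      responded <- as.integer(amplitudes[cbind(grid$fish_id,
                                               grid$trial_index)] > thr)
    }
    latency <- rep(NA_real_, n)
    resp <- which(responded == 1L)
    if (length(resp)) {
      is_long <- stats::runif(length(resp)) < long_latency_prob
      if (any(!is_long))
        latency[resp[!is_long]] <- rtrunc(sum(!is_long), latency_mean,
                                          latency_sd, slc_window[1L],
                                          slc_window[2L])
      if (any(is_long))
        latency[resp[is_long]] <- rtrunc(sum(is_long), long_latency_mean,
                                         long_latency_sd, slc_window[2L] +
                                           .Machine$double.eps * 100, 100)
    }
    direction <- rep("absent", n)
    direction[resp] <- sample(c("left", "right"), length(resp),
                              replace = TRUE)
    data.frame(fish_id = grid$fish_id, trial_index = grid$trial_index,
               intensity_db = protocol$intensity_db[grid$trial_index],
               frequency_hz = protocol$frequency,
               responded = responded, latency_ms = latency,
               direction = direction, condition = condition,
               stringsAsFactors = FALSE)
  })
}
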