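#' Transient kinetic parameters
#'
#' Bundles the parameters of the indicator transient waveform: a
#' difference-of-exponentials with a fast rise and a slower decay, the standard
#' shape of iGluSnFR/GCaMP responses. Decay time constants of roughly 100 ms
#' are typical for glutamate transients at Mauthner-cell inputs.
#'
#' @param amplitude Peak dF/F0 of the transient (dimensionless fraction, > 0;
#'   0 is allowed and yields a flat kernel).
#' @param tau_rise Rise time constant in seconds; must satisfy
#'   `0 < tau_rise < tau_decay`.
#' @param tau_decay Decay time constant in seconds.
#' @param onset_jitter_sd Standard deviation of stimulus-to-onset jitter in
#'   seconds (>= 0).
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(amplitude = 0.8, tau_rise = 0.01, tau_decay = 0.1)
#' @export
kinetic_params <- function(amplitude = 0.8, tau_rise = 0.010,
                           tau_decay = 0.100, onset_jitter_sd = 0) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, amplitude >= 0)
  if (!(tau_rise > 0 && tau_decay > tau_rise))
    stop("kinetic_params: need 0 < tau_rise < tau_decay")
  if (onset_jitter_sd < 0) stop("kinetic_params: onset_jitter_sd must be >= 0")
  structure(list(amplitude = amplitude, tau_rise = tau_rise,
                 tau_decay = tau_decay, onset_jitter_sd = onset_jitter_sd),
            class = "kinetic_params")
}

#' Synaptic resource-depletion parameters
#'
#' Phenomenological single-pool depletion model of short-term synaptic
#' depression: each stimulus releases a fraction `release_fraction_u` of the
#' currently available resource, which then recovers exponentially towards 1
#' with time constant `tau_recovery`. Relative release amplitude at stimulus n
#' equals the available resource just before it (floored at `floor`).
#'
#' @param release_fraction_u Fraction of the available resource released per
#'   stimulus, in `[0, 1]`.
#' @param tau_recovery Recovery time constant in seconds (> 0).
#' @param floor Minimum relative amplitude in `[0, 1]`.
#' @return An object of class `depletion_params`.
#' @export
depletion_params <- function(release_fraction_u = 0.2, tau_recovery = 5,
                             floor = 0) {
  if (release_fraction_u < 0 || release_fraction_u > 1)
    stop("depletion_params: release_fraction_u must lie in [0, 1]")
  if (tau_recovery <= 0) stop("depletion_params: tau_recovery must be > 0")
  if (floor < 0 || floor > 1) stop("depletion_params: floor must lie in [0, 1]")
  structure(list(release_fraction_u = release_fraction_u,
                 tau_recovery = tau_recovery, floor = floor),
            class = "depletion_params")
}

#' Recording noise parameters
#'
#' @param gaussian_sd SD of additive white Gaussian noise, in dF/F0 units.
#' @param drift_amplitude Amplitude of a slow sinusoidal baseline drift
#'   (dF/F0 units).
#' @param drift_period Period of the drift in seconds.
#' @param spontaneous_rate Rate of spontaneous release events, events per
#'   minute. Spontaneous glutamate release at the axon initial segment runs at
#'   about 2-4 events/minute in vivo; NMDA-receptor blockade roughly doubles it.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(gaussian_sd = 0.04, drift_amplitude = 0,
                         drift_period = 30, spontaneous_rate = 0) {
  if (gaussian_sd < 0) stop("noise_params: gaussian_sd must be >= 0")
  if (spontaneous_rate < 0) stop("noise_params: spontaneous_rate must be >= 0")
  if (drift_period <= 0) stop("noise_params: drift_period must be > 0")
  structure(list(gaussian_sd = gaussian_sd, drift_amplitude = drift_amplitude,
                 drift_period = drift_period,
                 spontaneous_rate = spontaneous_rate),
            class = "noise_params")
}

#' Stimulus protocol
#'
#' Describes a train of acoustic-vibrational stimuli. The habituation
#' protocols use 60 stimuli at interstimulus intervals of 1 s, 500 ms and
#' 250 ms (1, 2 and 4 Hz); intensity experiments use a ladder from 81.8 to
#' 91.7 dB with five stimuli per intensity.
#'
#' @param n_stimuli Number of stimuli (>= 1).
#' @param frequency Stimulation frequency in Hz; give either this or `isi`.
#' @param isi Interstimulus interval in seconds.
#' @param intensity_db Stimulus intensity in dB; either a scalar applied to
#'   every stimulus or a vector of length `n_stimuli`.
#' @param repeats_per_intensity Repeats per intensity step when an intensity
#'   ladder is used.
#' @return An object of class `stimulus_protocol` with fields `n_stimuli`,
#'   `frequency`, `isi`, `intensity_db`, `repeats_per_intensity`.
#' @examples
#' stimulus_protocol(60, frequency = 1)          # 1 Hz habituation train
#' stimulus_protocol(25, frequency = 0.2,
#'   intensity_db = rep(c(81.8, 83.8, 85.8, 89.8, 91.7), each = 5),
#'   repeats_per_intensity = 5)                  # intensity ladder
#' @export
stimulus_protocol <- function(n_stimuli = 60, frequency = NULL, isi = NULL,
                              intensity_db = 91.7, repeats_per_intensity = 1) {
  if (n_stimuli < 1) stop("stimulus_protocol: n_stimuli must be >= 1")
  if (is.null(frequency) && is.null(isi))
    stop("stimulus_protocol: give frequency or isi")
  if (is.null(isi)) isi <- 1 / frequency
  if (is.null(frequency)) frequency <- 1 / isi
  if (frequency <= 0) stop("stimulus_protocol: frequency must be > 0")
  if (length(intensity_db) == 1L) intensity_db <- rep(intensity_db, n_stimuli)
  if (length(intensity_db) != n_stimuli)
    stop("stimulus_protocol: intensity_db must be scalar or length n_stimuli")
  structure(list(n_stimuli = as.integer(n_stimuli), frequency = frequency,
                 isi = isi, intensity_db = intensity_db,
                 repeats_per_intensity = as.integer(repeats_per_intensity)),
            class = "stimulus_protocol")
}

#' Event-detection parameters
#'
#' Events are maximal runs of samples above the recording mean plus
#' `k_sd` standard deviations; the field-standard threshold is mean + 2 SD.
#'
#' @param k_sd SD multiplier for the detection threshold (> 0, default 2).
#' @param min_duration Minimum run length in samples (default 5, i.e. 20 ms at
#'   250 Hz) to suppress single-sample noise crossings.
#' @param refractory Merge window in seconds: events whose onsets follow the
#'   previous event's end by less than this are merged (default 0.2).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(k_sd = 2, min_duration = 5, refractory = 0.2) {
  if (k_sd <= 0) stop("detection_params: k_sd must be > 0")
  if (min_duration < 1) stop("detection_params: min_duration must be >= 1")
  if (refractory < 0) stop("detection_params: refractory must be >= 0")
  structure(list(k_sd = k_sd, min_duration = as.integer(min_duration),
                 refractory = refractory),
            class = "detection_params")
}

#' Motion-correction parameters
#'
#' @param reference_lines Number of initial time points averaged to build the
#'   X-Y reference profile (default 150).
#' @param max_shift Maximum correctable integer shift in samples (default 5).
#' @param discard_shift Shifts beyond this many samples flag the frame for
#'   discard (default 5; must be >= max_shift).
#' @param smooth_sigma Gaussian smoothing SD in samples (default 2).
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(reference_lines = 150, max_shift = 5,
                          discard_shift = 5, smooth_sigma = 2) {
  if (reference_lines < 1) stop("motion_params: reference_lines must be >= 1")
  if (max_shift < 0) stop("motion_params: max_shift must be >= 0")
  if (discard_shift < max_shift)
    stop("motion_params: discard_shift must be >= max_shift")
  structure(list(reference_lines = as.integer(reference_lines),
                 max_shift = as.integer(max_shift),
                 discard_shift = as.integer(discard_shift),
                 smooth_sigma = smooth_sigma),
            class = "motion_params")
}
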