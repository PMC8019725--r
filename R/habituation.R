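# Stimulus-locked amplitude analysis: intensity-response curves, short-term
# depression curves, activation probability, release-threshold estimation,
# and exponential habituation fits.

#' Extract stimulus-locked peak amplitudes
#'
#' For each stimulus onset, the maximum dF/F0 in the half-open window
#' `(onset, onset + window]`.
#'
#' @param trace A dF/F0 [trace_recording()] or numeric vector (then supply
#'   `sampling_rate`).
#' @param onsets Stimulus onsets in seconds; defaults to the recording's.
#' @param window Peak-search window in seconds; must not exceed the ISI so
#'   windows do not overlap. Default `0.5`.
#' @param sampling_rate Required for a bare vector.
#' @return Numeric vector, one peak per onset.
#' @export
stimulus_locked_peaks <- function(trace, onsets = NULL, window = 0.5,
                                  sampling_rate = NULL) {
  if (inherits(trace, "trace_recording")) {
    v <- trace_values(trace)
    times <- trace$times
    if (is.null(onsets)) onsets <- trace$stimulus_onsets
  } else {
    if (is.null(sampling_rate))
      stop("stimulus_locked_peaks: sampling_rate required for a bare vector")
    v <- as.numeric(trace)
    times <- (seq_along(v) - 1L) / sampling_rate
  }
  if (!length(onsets)) stop("stimulus_locked_peaks: no stimulus onsets")
  onsets <- sort(onsets)
  if (length(onsets) > 1L && window > min(diff(onsets)) + 1e-9)
    stop("stimulus_locked_peaks: window exceeds the ISI (overlapping windows)")
  t_end <- times[length(times)]
  vapply(onsets, function(o) {
    if (o + window > t_end + 1e-9)
      stop("stimulus_locked_peaks: onset window extends beyond the trace end")
    sel <- times > o & times <= o + window
    if (!any(sel))
      stop("stimulus_locked_peaks: empty peak window at onset ", o)
    max(v[sel])
  }, numeric(1L))
}

#' Build an intensity-response curve
#'
#' Per fish, the peaks at each intensity (typically five repeats per step of
#' the 81.8-91.7 dB ladder) are averaged and divided by that fish's mean peak
#' at the reference intensity (91.7 dB); the cohort mean and SD per intensity
#' are then reported. Fish with a non-positive reference response are
#' excluded with a warning.
#'
#' @param peaks Data.frame with columns `fish_id`, `intensity_db`, `peak`.
#' @param reference_db Reference intensity (default 91.7).
#' @return A data.frame (`intensity_curve`): `intensity_db`,
#'   `normalized_mean`, `sd`, `n_fish`. Attribute `excluded_fish` lists any
#'   excluded fish ids.
#' @export
build_intensity_curve <- function(peaks, reference_db = 91.7) {
  stopifnot(all(c("fish_id", "intensity_db", "peak") %in% names(peaks)))
  if (!any(abs(peaks$intensity_db - reference_db) < 1e-9))
    stop("build_intensity_curve: reference intensity absent from the data")
  per_fish <- stats::aggregate(peak ~ fish_id + intensity_db, peaks, mean)
  ref <- per_fish[abs(per_fish$intensity_db - reference_db) < 1e-9, ]
  bad <- ref$fish_id[ref$peak <= 0]
  if (length(bad)) {
    warning("build_intensity_curve: excluding fish with non-positive ",
            "reference response: ", paste(bad, collapse = ", "))
    per_fish <- per_fish[!per_fish$fish_id %in% bad, ]
    ref <- ref[!ref$fish_id %in% bad, ]
  }
  if (!nrow(ref)) stop("build_intensity_curve: no usable reference responses")
  per_fish$norm <- per_fish$peak /
    ref$peak[match(per_fish$fish_id, ref$fish_id)]
  agg <- stats::aggregate(norm ~ intensity_db, per_fish, function(x)
    c(mean = mean(x), sd = stats::sd(x), n = length(x)))
  out <- data.frame(intensity_db = agg$intensity_db,
                    normalized_mean = agg$norm[, "mean"],
                    sd = agg$norm[, "sd"], n_fish = agg$norm[, "n"])
  out <- out[order(out$intensity_db), ]
  rownames(out) <- NULL
  attr(out, "excluded_fish") <- bad
  class(out) <- c("intensity_curve", "data.frame")
  out
}

#' Build a short-term depression curve
#'
#' Peak fluorescence values of every `bin_k` consecutive stimulus-locked
#' events are averaged per fish and normalised to that fish's mean over the
#' first `bin_k` stimuli (so bin 1 is exactly 1 for every fish), then
#' averaged across the cohort. With the standard 60-stimulus protocol and
#' `bin_k = 5` this yields 12 bins.
#'
#' @param peaks Numeric matrix (fish x stimulus) or a vector for a single
#'   fish; the stimulus count must be divisible by `bin_k`.
#' @param bin_k Bin size in stimuli (default 5).
#' @param frequency,roi,condition Optional labels stored on the result.
#' @return A data.frame (`depression_curve`): `bin_index`, `normalized_mean`,
#'   `sd`, `n_fish`, `frequency`, `roi`, `condition`. Attribute `per_fish`
#'   holds the fish x bin matrix of normalised values.
#' @export
depression_curve <- function(peaks, bin_k = 5, frequency = NA_real_,
                             roi = NA_character_, condition = NA_character_) {
  if (!is.matrix(peaks)) peaks <- matrix(peaks, nrow = 1L)
  n_stim <- ncol(peaks)
  if (n_stim < bin_k)
    stop("depression_curve: fewer peaks than bin_k")
  if (n_stim %% bin_k != 0)
    stop("depression_curve: stimulus count must be divisible by bin_k")
  bm <- apply(peaks, 1L, bin_by_factor, k = bin_k)
  binned <- if (is.matrix(bm)) t(bm) else matrix(bm, ncol = 1L)
  norm <- binned / binned[, 1L]
  out <- data.frame(bin_index = seq_len(ncol(norm)),
                    normalized_mean = colMeans(norm),
                    sd = apply(norm, 2L, stats::sd),
                    n_fish = nrow(norm), frequency = frequency,
                    roi = roi, condition = condition)
  attr(out, "per_fish") <- norm
  class(out) <- c("depression_curve", "data.frame")
  out
}

#' Probability of cell activation across repeated trials
#'
#' A trial counts as an activation when any post-stimulus sample exceeds that
#' trial's baseline mean plus `k_sd` baseline standard deviations.
#'
#' @param trials List of dF/F0 [trace_recording()]s (one per trial), or a
#'   list of lists `list(baseline =, post =)` of numeric samples.
#' @param params A [detection_params()] (only `k_sd` is used).
#' @param baseline_window Baseline duration (s) before the first stimulus
#'   when recordings are given.
#' @return Fraction of trials with supra-threshold activity, with attribute
#'   `n_trials`.
#' @export
activation_probability <- function(trials, params = detection_params(),
                                   baseline_window = 0.5) {
  if (!length(trials)) stop("activation_probability: no trials")
  active <- vapply(trials, function(tr) {
    if (inherits(tr, "trace_recording")) {
      if (!length(tr$stimulus_onsets))
        stop("activation_probability: recording lacks stimulus onsets")
      on <- min(tr$stimulus_onsets)
      v <- trace_values(tr)
      base <- v[tr$times >= on - baseline_window & tr$times < on]
      post <- v[tr$times >= on]
    } else {
      base <- tr$baseline
      post <- tr$post
    }
    s <- stats::sd(base)
    if (is.na(s) || s == 0)
      stop("activation_probability: zero-variance baseline")
    any(post > mean(base) + params$k_sd * s)
  }, logical(1L))
  p <- mean(active)
  attr(p, "n_trials") <- length(trials)
  p
}

#' Estimate the release threshold for escape
#'
#' Rescales per-trial release amplitudes to their maximum and finds the cut
#' that best separates escape from no-escape trials (maximum classification
#' accuracy over an exhaustive scan of candidate cuts; the optimal interval's
#' midpoint is reported). An exact binomial test of the achieved accuracy
#' against the majority-class base rate flags thresholds that carry no
#' information about the outcome.
#'
#' @param amplitudes Per-trial release peak amplitudes (max > 0).
#' @param escapes Per-trial 0/1 escape outcomes.
#' @param method `"cut"` (accuracy-maximising scan, default) or `"logistic"`
#'   (threshold at the 50% point of a logistic fit).
#' @return A list: `threshold` (fraction of the maximal amplitude),
#'   `accuracy`, `informative` (logical), `p_value` (accuracy vs. base
#'   rate), `method`.
#' @export
estimate_release_threshold <- function(amplitudes, escapes,
                                       method = c("cut", "logistic")) {
  method <- match.arg(method)
  stopifnot(length(amplitudes) == length(escapes))
  escapes <- as.integer(escapes)
  if (all(escapes == 1L) || all(escapes == 0L))
    stop("estimate_release_threshold: need both escape and no-escape trials")
  if (max(amplitudes) <= 0)
    stop("estimate_release_threshold: maximal amplitude must be > 0")
  x <- amplitudes / max(amplitudes)
  n <- length(x)
  base_rate <- max(mean(escapes), 1 - mean(escapes))
  if (method == "logistic") {
    # perfect separation is legitimate here (the warning-free cut method is
    # the default); the 50% point still lies in the separating gap
    fit <- suppressWarnings(stats::glm(escapes ~ x,
                                       family = stats::binomial()))
    b <- stats::coef(fit)
    thr <- if (abs(b[2L]) > 1e-12) unname(-b[1L] / b[2L]) else NA_real_
    acc <- mean((x > thr) == (escapes == 1L))
  } else {
    # exhaustive scan over cuts between consecutive distinct amplitudes
    xs <- sort(unique(x))
    cand <- c(xs[1L] - 1e-9, (xs[-1L] + xs[-length(xs)]) / 2, 1 + 1e-9)
    accs <- vapply(cand, function(cut) mean((x > cut) == (escapes == 1L)),
                   numeric(1L))
    best <- max(accs)
    opt <- which(accs >= best - 1e-12)
    # ties: midpoint of the contiguous optimal interval
    thr <- mean(range(cand[opt]))
    acc <- best
  }
  p <- stats::binom.test(round(acc * n), n, base_rate,
                         alternative = "greater")$p.value
  list(threshold = thr, accuracy = acc, informative = p < 0.05,
       p_value = p, method = method)
}

#' Fit an exponential habituation curve
#'
#' Least-squares fit of `p(n) = p_inf + (1 - p_inf) * exp(-n / k)` to a
#' response-probability series, the standard description of the progressive
#' decline of startle probability under repeated stimulation.
#'
#' @param p Response probabilities per trial index (in `[0, 1]`, >= 10
#'   trials).
#' @param trial_index Trial indices; defaults to `1:length(p)`.
#' @return A list: `k` (rate constant in trials), `p_floor` (asymptote),
#'   `fitted`, `rss`, `converged`, `poor_fit` (probability series does not
#'   decline), `no_habituation` (k effectively infinite).
#' @export
fit_exponential_habituation <- function(p, trial_index = seq_along(p)) {
  if (length(p) < 10L)
    stop("fit_exponential_habituation: need >= 10 trials")
  if (any(p < 0 | p > 1))
    stop("fit_exponential_habituation: probabilities must lie in [0, 1]")
  n <- trial_index
  third <- max(1L, length(p) %/% 3L)
  declining <- mean(p[seq_len(third)]) >
    mean(p[(length(p) - third + 1L):length(p)])
  k_max <- 1e4
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ pf + (1 - pf) * exp(-n / k),
                      start = list(pf = max(min(p), 1e-3), k = length(p) / 4),
                      lower = c(pf = 0, k = 1e-3),
                      upper = c(pf = 1, k = k_max),
                      control = minpack.lm::nls.lm.control(maxiter = 200,
                                                           ftol = 1e-12,
                                                           ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(k = NA_real_, p_floor = NA_real_, fitted = rep(NA_real_,
                length(p)), rss = Inf, converged = FALSE,
                poor_fit = TRUE, no_habituation = !declining))
  cf <- stats::coef(fit)
  list(k = unname(cf[["k"]]), p_floor = unname(cf[["pf"]]),
       fitted = as.numeric(stats::fitted(fit)),
       rss = sum(stats::residuals(fit)^2), converged = TRUE,
       poor_fit = !declining,
       no_habituation = cf[["k"]] >= 0.99 * k_max || !declining)
}
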