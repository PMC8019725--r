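#' Construct a fluorescence trace recording
#'
#' Container for a uniformly sampled fluorescence time series from one region
#' of interest (possibly several parallel scan lines), plus the stimulus onsets
#' needed for stimulus-locked analysis.
#'
#' @param times Sample times in seconds, a strictly increasing uniform grid.
#' @param values Numeric vector, or matrix with one column per scan line.
#' @param sampling_rate Sampling rate in Hz (250 for glutamate line scans,
#'   20 for calcium).
#' @param roi_label One of `"LD"` (lateral dendrite), `"AIS"` (axon initial
#'   segment) or `"SFN_soma"`.
#' @param stimulus_onsets Stimulus onset times in seconds (may be empty).
#' @param condition `"vehicle"` or `"drug"`.
#' @param units `"raw"` fluorescence or `"dff"` (dF/F0).
#' @return An object of class `trace_recording`.
#' @export
trace_recording <- function(times, values, sampling_rate,
                            roi_label = c("AIS", "LD", "SFN_soma"),
                            stimulus_onsets = numeric(),
                            condition = c("vehicle", "drug"),
                            units = c("raw", "dff")) {
  roi_label <- match.arg(roi_label)
  condition <- match.arg(condition)
  units <- match.arg(units)
  values <- as.matrix(values)
  if (length(times) != nrow(values))
    stop("trace_recording: times and values lengths differ")
  if (length(times) < 2L) stop("trace_recording: need at least 2 samples")
  dt <- diff(times)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stop(sprintf("trace_recording: times not strictly increasing at row %d", bad))
  }
  if (max(abs(dt - 1 / sampling_rate)) > 1e-9 * max(abs(times), 1)) {
    bad <- which.max(abs(dt - 1 / sampling_rate)) + 1L
    stop(sprintf("trace_recording: non-uniform time grid at row %d", bad))
  }
  if (length(stimulus_onsets) &&
      (min(stimulus_onsets) < times[1L] - 1e-9 ||
       max(stimulus_onsets) > times[length(times)] + 1e-9))
    stop("trace_recording: stimulus_onsets outside the recorded interval")
  structure(list(times = as.numeric(times), values = values,
                 sampling_rate = sampling_rate, roi_label = roi_label,
                 stimulus_onsets = as.numeric(stimulus_onsets),
                 condition = condition, units = units),
            class = "trace_recording")
}

#' @export
print.trace_recording <- function(x, ...) {
  cat(sprintf("trace_recording: %s (%s), %d samples x %d line(s) at %g Hz, %.2f s, %d stimuli, units=%s\n",
              x$roi_label, x$condition, nrow(x$values), ncol(x$values),
              x$sampling_rate, x$times[length(x$times)] - x$times[1L],
              length(x$stimulus_onsets), x$units))
  invisible(x)
}

# mean across scan lines as a plain numeric vector
trace_values <- function(rec) {
  if (ncol(rec$values) == 1L) as.numeric(rec$values[, 1L])
  else rowMeans(rec$values)
}
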