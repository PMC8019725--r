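# Raw recordings -> motion-corrected, smoothed dF/F0 traces.

#' Compute dF/F0 relative to a pre-stimulus baseline
#'
#' The baseline F0 is the mean fluorescence over a window immediately
#' preceding the first stimulus onset; the output is `(F - F0) / F0` per scan
#' line. dF/F0 is invariant to multiplicative gain on the raw trace.
#'
#' @param trace A raw [trace_recording()] with at least one stimulus onset
#'   (or pass `baseline_end` explicitly).
#' @param baseline_window Baseline duration in seconds, taken immediately
#'   before the first stimulus (default 0.5).
#' @param baseline_end End of the baseline window in seconds; defaults to the
#'   first stimulus onset.
#' @return A [trace_recording()] with `units = "dff"`.
#' @examples
#' s <- simulate_session(stimulus_protocol(5, frequency = 1),
#'                       kinetic_params(0.8, 0.01, 0.1),
#'                       noise = noise_params(gaussian_sd = 0),
#'                       seed = 1, emit = "raw")
#' d <- compute_dff(s$recording)
#' max(d$values)  # ~ 0.8
#' @export
compute_dff <- function(trace, baseline_window = 0.5, baseline_end = NULL) {
  stopifnot(inherits(trace, "trace_recording"))
  if (is.null(baseline_end)) {
    if (!length(trace$stimulus_onsets))
      stop("compute_dff: no stimulus onsets; supply baseline_end")
    baseline_end <- min(trace$stimulus_onsets)
  }
  sel <- trace$times >= baseline_end - baseline_window &
    trace$times < baseline_end
  if (!any(sel)) stop("compute_dff: empty baseline window")
  vals <- trace$values
  for (j in seq_len(ncol(vals))) {
    f0 <- mean(vals[sel, j])
    if (f0 <= 0) stop("compute_dff: baseline mean <= 0")
    vals[, j] <- (vals[, j] - f0) / f0
  }
  out <- trace
  out$values <- vals
  out$units <- "dff"
  out
}

# unit-area discrete Gaussian kernel, truncated at 4 sigma
gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k / sum(k)
}

#' Gaussian-smooth a trace
#'
#' Convolution with a unit-area discrete Gaussian kernel; edges are handled by
#' reflection padding so baseline levels at the trace ends are preserved.
#' `sigma = 0` is the identity.
#'
#' @param trace A [trace_recording()] or a numeric vector.
#' @param sigma Kernel SD in samples (>= 0, default 2).
#' @return Object of the same type as the input, smoothed.
#' @export
gaussian_smooth <- function(trace, sigma = 2) {
  if (sigma < 0) stop("gaussian_smooth: sigma must be >= 0")
  smooth_vec <- function(v) {
    if (sigma == 0) return(v)
    k <- gaussian_kernel(sigma)
    half <- (length(k) - 1L) %/% 2L
    n <- length(v)
    pad <- c(v[pmin(half, n - 1L):1 + 1L], v, v[n - 1L:pmin(half, n - 1L)])
    out <- stats::filter(pad, k, method = "convolution", sides = 2L)
    as.numeric(out[(half + 1L):(half + n)])
  }
  if (inherits(trace, "trace_recording")) {
    trace$values <- apply(trace$values, 2L, smooth_vec)
    trace
  } else smooth_vec(trace)
}

#' Select the best-matching Z plane for a frame
#'
#' Registers a single frame against a reference Z-stack by normalised
#' cross-correlation (Pearson correlation of pixel intensities) and returns
#' the index of the maximally correlated slice. Ties are broken towards the
#' previously selected plane when given, otherwise towards the lower index.
#'
#' @param stack A [zstack()].
#' @param frame Numeric matrix with the same in-plane dimensions as the
#'   slices.
#' @param previous Optional previously selected plane index (tie-break).
#' @return A list with `plane` (1-based slice index) and `score` (the
#'   correlation).
#' @export
select_z_plane <- function(stack, frame, previous = NULL) {
  stopifnot(inherits(stack, "zstack"))
  if (!all(dim(frame) == dim(stack$slices[[1L]])))
    stop("select_z_plane: frame dimensions differ from stack slices")
  fv <- as.numeric(frame)
  if (stats::sd(fv) == 0)
    stop("select_z_plane: zero-variance frame; correlation undefined")
  if (stack$n_slices == 1L)
    return(list(plane = 1L, score = stats::cor(fv,
                                as.numeric(stack$slices[[1L]]))))
  scores <- vapply(stack$slices,
                   function(s) stats::cor(fv, as.numeric(s)), numeric(1L))
  best <- max(scores)
  cand <- which(scores >= best - 1e-12)
  plane <- if (!is.null(previous) && previous %in% cand) as.integer(previous)
    else min(cand)
  list(plane = as.integer(plane), score = scores[plane])
}

#' Correct X-Y drift in a line-scan matrix
#'
#' The reference spatial profile is the mean over the first
#' `params$reference_lines` time points. Each time point's spatial profile is
#' shifted by the integer number of samples (searched within
#' `+/- params$max_shift`) that maximises its correlation with the reference,
#' and frames whose best shift exceeds `params$discard_shift` are flagged for
#' discard.
#'
#' @param linescan_matrix Numeric matrix, scan-line samples (rows) x time
#'   points (columns).
#' @param params A [motion_params()].
#' @return A list with `corrected` (matrix), `shifts` (integer per time
#'   point, the detected drift), and `discard` (logical per time point).
#' @export
correct_xy_drift <- function(linescan_matrix, params = motion_params()) {
  stopifnot(is.matrix(linescan_matrix), inherits(params, "motion_params"))
  n_pix <- nrow(linescan_matrix)
  n_t <- ncol(linescan_matrix)
  if (n_t < params$reference_lines)
    stop("correct_xy_drift: fewer time points than reference_lines")
  if (n_pix < 2L * params$max_shift + 1L)
    stop("correct_xy_drift: scan line shorter than 2*max_shift + 1")
  ref <- rowMeans(linescan_matrix[, seq_len(params$reference_lines),
                                  drop = FALSE])
  # search beyond discard_shift so over-limit drift is detected, not clipped
  search <- min(params$discard_shift + max(params$max_shift, 1L), n_pix - 2L)
  cand <- (-search):search
  shifts <- integer(n_t)
  corrected <- linescan_matrix
  discard <- logical(n_t)
  for (t in seq_len(n_t)) {
    prof <- linescan_matrix[, t]
    # correlation of the profile shifted back by -s against the reference,
    # on the overlap region only
    cors <- vapply(cand, function(s) {
      if (s >= 0) {
        a <- prof[(1L + s):n_pix]; b <- ref[1L:(n_pix - s)]
      } else {
        a <- prof[1L:(n_pix + s)]; b <- ref[(1L - s):n_pix]
      }
      if (stats::sd(a) == 0 || stats::sd(b) == 0) -Inf else stats::cor(a, b)
    }, numeric(1L))
    best <- cand[order(abs(cand), cand)][which.max(
      cors[order(abs(cand), cand)])]  # prefer the smallest |shift| on ties
    shifts[t] <- best
    if (abs(best) > params$discard_shift) {
      discard[t] <- TRUE
    } else if (best != 0L) {
      corrected[, t] <- shift_profile(prof, -best)
    }
  }
  list(corrected = corrected, shifts = shifts, discard = discard)
}

#' Bin a series by non-overlapping averaging
#'
#' Means of `k` consecutive samples; a trailing remainder shorter than `k` is
#' dropped. With `k = 1` the input is returned unchanged.
#'
#' @param series Numeric vector.
#' @param k Bin size (1 <= k <= length(series)).
#' @return Numeric vector of length `floor(length(series) / k)`.
#' @examples
#' bin_by_factor(1:10, 5)  # c(3, 8)
#' @export
bin_by_factor <- function(series, k) {
  if (k < 1) stop("bin_by_factor: k must be >= 1")
  n <- length(series)
  if (k > n) stop("bin_by_factor: k exceeds series length")
  k <- as.integer(k)
  if (k == 1L) return(series)
  m <- (n %/% k) * k
  colMeans(matrix(series[seq_len(m)], nrow = k))
}
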