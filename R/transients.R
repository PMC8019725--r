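# Release-event detection, biexponential kinetic fitting with quality
# control, and spontaneous-event statistics.

# peak-normalised difference of exponentials; 0 before onset t0
biexp_model <- function(t, amplitude, tau_rise, tau_decay, onset = 0) {
  tr <- min(tau_rise, tau_decay)
  td <- max(tau_rise, tau_decay)
  tstar <- kernel_peak_time(tr, td)
  peak <- exp(-tstar / td) - exp(-tstar / tr)
  tt <- pmax(t - onset, 0)
  amplitude * (exp(-tt / td) - exp(-tt / tr)) / peak *
    as.numeric(t >= onset)
}

#' Detect release events in a dF/F0 trace
#'
#' Events are maximal runs of at least `min_duration` consecutive samples
#' above the detection threshold, defined as the mean of the whole recording
#' plus `k_sd` times its standard deviation. Events whose onset follows the
#' previous event's end by less than `refractory` seconds are merged.
#' Detection is invariant to adding a constant to the trace and to positive
#' rescaling.
#'
#' @param trace A dF/F0 [trace_recording()] (scan lines are averaged), or a
#'   numeric vector with `sampling_rate` supplied.
#' @param params A [detection_params()].
#' @param sampling_rate Required when `trace` is a bare numeric vector.
#' @return A data.frame with one row per event: `onset_s`, `peak_time_s`,
#'   `peak_value`, `end_s`. A zero-variance trace yields zero rows with
#'   attribute `warning` set (and a warning).
#' @export
detect_events <- function(trace, params = detection_params(),
                          sampling_rate = NULL) {
  if (inherits(trace, "trace_recording")) {
    v <- trace_values(trace)
    times <- trace$times
    sampling_rate <- trace$sampling_rate
  } else {
    if (is.null(sampling_rate))
      stop("detect_events: sampling_rate required for a bare vector")
    v <- as.numeric(trace)
    times <- (seq_along(v) - 1L) / sampling_rate
  }
  empty <- data.frame(onset_s = numeric(), peak_time_s = numeric(),
                      peak_value = numeric(), end_s = numeric())
  s <- stats::sd(v)
  if (s == 0) {
    warning("detect_events: zero-variance trace; threshold undefined")
    attr(empty, "warning") <- "zero-variance trace"
    return(empty)
  }
  thr <- mean(v) + params$k_sd * s
  above <- v > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= params$min_duration
  if (!any(keep)) return(empty)
  on_i <- starts[keep]
  off_i <- ends[keep]
  # merge runs separated by less than the refractory period
  merged_on <- on_i[1L]; merged_off <- off_i[1L]
  if (length(on_i) > 1L) {
    for (j in 2L:length(on_i)) {
      gap <- times[on_i[j]] - times[merged_off[length(merged_off)]]
      if (gap < params$refractory) {
        merged_off[length(merged_off)] <- off_i[j]
      } else {
        merged_on <- c(merged_on, on_i[j])
        merged_off <- c(merged_off, off_i[j])
      }
    }
  }
  peak_idx <- mapply(function(a, b) a - 1L + which.max(v[a:b]),
                     merged_on, merged_off)
  data.frame(onset_s = times[merged_on], peak_time_s = times[peak_idx],
             peak_value = v[peak_idx], end_s = times[merged_off])
}

#' Fit a biexponential transient to an extracted event
#'
#' The segment is binned by `bin_k` and a peak-normalised difference of
#' exponentials `A * c * (exp(-(t - t0)/tau_decay) - exp(-(t - t0)/tau_rise))`
#' is least-squares fitted (Levenberg-Marquardt) to the binned series.
#' Parameters are ordered so `tau_rise < tau_decay` (the waveform is
#' symmetric under relabelling). The fit MSE is evaluated on the binned
#' series with dF/F0 expressed in percent; fits that fail to converge or
#' exceed `mse_max` are rejected.
#'
#' @param segment Numeric dF/F0 values starting at the event onset.
#' @param dt Sample interval in seconds.
#' @param bin_k Binning factor applied before fitting (default 5).
#' @param mse_max Acceptance ceiling for the MSE in percent^2 units
#'   (default 10).
#' @param model `"rise-decay"` (difference of exponentials, the indicator
#'   transient shape) or `"double-decay"` (sum of two decaying exponentials).
#' @return A one-row data.frame (`transient_fit`): `amplitude`, `tau_rise`,
#'   `tau_decay`, `onset`, `mse`, `accepted`, `converged`. On
#'   non-convergence `mse` is `Inf` and `accepted` is `FALSE`.
#' @export
fit_biexponential <- function(segment, dt, bin_k = 5, mse_max = 10,
                              model = c("rise-decay", "double-decay")) {
  model <- match.arg(model)
  segment <- as.numeric(segment)
  if (length(segment) < 3L * bin_k)
    stop("fit_biexponential: segment too short to bin and fit")
  y <- bin_by_factor(segment, bin_k)
  nb <- length(y)
  # sample times of the unbinned segment; the model is averaged over each
  # bin so binning attenuates the fit and the data identically
  ts <- (seq_len(nb * bin_k) - 1L) * dt
  tb <- bin_by_factor(ts, bin_k)
  failed <- data.frame(amplitude = NA_real_, tau_rise = NA_real_,
                       tau_decay = NA_real_, onset = NA_real_, mse = Inf,
                       accepted = FALSE, converged = FALSE)
  ip <- which.max(y)
  a0 <- max(y[ip], 1e-3)
  tp <- max(tb[ip], 2 * dt)
  below <- which(y[ip:nb] <= 0.37 * y[ip])
  td0 <- if (length(below)) max(tb[ip - 1L + below[1L]] - tb[ip], 3 * dt)
    else max(tb[nb] - tb[ip], 3 * dt)
  tr0 <- max(tp / 3, dt / 2)
  if (tr0 >= td0) tr0 <- td0 / 3
  pointfun <- if (model == "rise-decay") {
    function(t, A, tr, td, t0) biexp_model(t, A, tr, td, t0)
  } else {
    function(t, A, tr, td, t0) {
      tt <- pmax(t - t0, 0)
      (A * exp(-tt / td) + 0.5 * A * exp(-tt / tr)) * as.numeric(t >= t0)
    }
  }
  fitfun <- function(t, A, tr, td, t0)
    bin_by_factor(pointfun(ts, A, tr, td, t0), bin_k)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fitfun(tb, A, tr, td, t0),
      start = list(A = a0, tr = tr0, td = td0, t0 = 0),
      lower = c(A = 0, tr = dt / 20, td = dt / 10, t0 = -5 * bin_k * dt),
      upper = c(A = 10 * a0, tr = 10 * td0, td = 100 * td0, t0 = tp),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-9,
                                           ptol = 1e-9)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed)
  cf <- stats::coef(fit)
  tr <- min(cf[["tr"]], cf[["td"]])
  td <- max(cf[["tr"]], cf[["td"]])
  mse <- mean((100 * stats::residuals(fit))^2)
  out <- data.frame(amplitude = cf[["A"]], tau_rise = tr, tau_decay = td,
                    onset = cf[["t0"]], mse = mse,
                    accepted = is.finite(mse) && mse <= mse_max && tr < td,
                    converged = TRUE)
  class(out) <- c("transient_fit", "data.frame")
  out
}

#' Spontaneous event rate
#'
#' @param events Detected events (a data.frame from [detect_events()]) or an
#'   event count.
#' @param duration Recording duration in seconds (> 0).
#' @return Events per minute.
#' @examples
#' spontaneous_rate(4, 60)  # 4 events in one minute
#' @export
spontaneous_rate <- function(events, duration) {
  if (duration <= 0) stop("spontaneous_rate: duration must be > 0")
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  60 * n / duration
}

#' Compare transient decay time constants across groups
#'
#' One-way ANOVA over the decay time constants of accepted fits, grouped for
#' example by region of interest and condition; normality of each group is
#' screened with the Shapiro-Wilk test and reported alongside.
#'
#' @param groups Named list of numeric vectors (decay time constants in
#'   seconds), at least two groups of at least two values each.
#' @return A list: `f_statistic`, `p_value`, `df`, `group_means`,
#'   `group_sds`, `group_n`, `shapiro_p` (named; NA for groups outside the
#'   test's 3-5000 size range).
#' @export
compare_time_constants <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("compare_time_constants: need at least two groups")
  if (any(vapply(groups, length, integer(1L)) < 2L))
    stop("compare_time_constants: every group needs at least two fits")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, integer(1L)))))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1L]]
  shapiro_p <- vapply(groups, function(g) {
    if (length(g) >= 3L && length(g) <= 5000L && stats::sd(g) > 0)
      stats::shapiro.test(g)$p.value else NA_real_
  }, numeric(1L))
  list(f_statistic = tab[["F value"]][1L], p_value = tab[["Pr(>F)"]][1L],
       df = tab[["Df"]],
       group_means = vapply(groups, mean, numeric(1L)),
       group_sds = vapply(groups, stats::sd, numeric(1L)),
       group_n = vapply(groups, length, integer(1L)),
       shapiro_p = shapiro_p)
}
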