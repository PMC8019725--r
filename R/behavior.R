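# Behavioural-table analytics: latency classification, habituation
# probability series, distribution comparisons, laterality, group tests.

#' Classify escape latencies
#'
#' Short-latency C-bends (SLC, the Mauthner-cell-mediated escape) occur 2-12
#' ms after stimulus onset; responses outside that window are long-latency
#' (LLC), and trials without a response are `none`. Window bounds are
#' inclusive.
#'
#' @param trials Behaviour-trial data.frame with columns `responded` and
#'   `latency_ms` (ms; `NA` for non-responders).
#' @param slc_window Inclusive SLC window in ms (default `c(2, 12)`).
#' @return Character vector of per-trial labels `"SLC"`, `"LLC"` or
#'   `"none"`.
#' @export
classify_latencies <- function(trials, slc_window = c(2, 12)) {
  stopifnot(all(c("responded", "latency_ms") %in% names(trials)))
  lat <- trials$latency_ms
  if (any(!is.na(lat) & lat < 0))
    stop("classify_latencies: negative latency")
  out <- rep("none", nrow(trials))
  resp <- trials$responded == 1L
  out[resp] <- "LLC"
  out[resp & !is.na(lat) & lat >= slc_window[1L] & lat <= slc_window[2L]] <-
    "SLC"
  out
}

#' Escape-probability series across trials
#'
#' The fraction of fish responding at each trial index, the series to which
#' [fit_exponential_habituation()] is applied. Requires a complete (non-
#' ragged) cohort: every fish must contribute every trial index.
#'
#' @param trials Behaviour-trial data.frame with `fish_id`, `trial_index`,
#'   `responded`.
#' @return A data.frame: `trial_index`, `probability`, `n_fish`; attribute
#'   `low_n` is `TRUE` for a single-fish cohort.
#' @export
habituation_probability_series <- function(trials) {
  stopifnot(all(c("fish_id", "trial_index", "responded") %in% names(trials)))
  tab <- table(trials$fish_id, trials$trial_index)
  if (any(tab != 1L))
    stop("habituation_probability_series: ragged cohort; every fish must ",
         "have every trial index exactly once")
  agg <- stats::aggregate(responded ~ trial_index, trials, mean)
  n_fish <- length(unique(trials$fish_id))
  out <- data.frame(trial_index = agg$trial_index,
                    probability = agg$responded, n_fish = n_fish)
  out <- out[order(out$trial_index), ]
  rownames(out) <- NULL
  attr(out, "low_n") <- n_fish < 2L
  out
}

#' Compare two latency distributions (Kolmogorov-Smirnov)
#'
#' Two-sample KS test on empirical latency distributions, e.g. vehicle vs.
#' drug-treated responders.
#'
#' @param a,b Numeric latency samples (each of size >= 5).
#' @return A list: `statistic` (D), `p_value`, `n` (sample sizes).
#' @export
compare_latency_distributions <- function(a, b) {
  if (length(a) < 5L || length(b) < 5L)
    stop("compare_latency_distributions: each sample needs >= 5 values")
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n = c(length(a), length(b)))
}

#' Exact binomial test of escape laterality
#'
#' Tests whether escape direction (ipsilateral vs. contralateral counts)
#' deviates from the 50:50 split expected when the stimulus carries no
#' directional information.
#'
#' @param ipsilateral_count,contralateral_count Non-negative counts, total
#'   >= 1.
#' @return A list: `p_value`, `estimate` (ipsilateral fraction), `counts`.
#' @examples
#' laterality_test(15, 15)$p_value  # 1
#' @export
laterality_test <- function(ipsilateral_count, contralateral_count) {
  if (ipsilateral_count < 0 || contralateral_count < 0)
    stop("laterality_test: counts must be >= 0")
  tot <- ipsilateral_count + contralateral_count
  if (tot < 1) stop("laterality_test: total count must be >= 1")
  bt <- stats::binom.test(ipsilateral_count, tot, p = 0.5)
  list(p_value = bt$p.value, estimate = unname(bt$estimate),
       counts = c(ipsilateral = ipsilateral_count,
                  contralateral = contralateral_count))
}

# significance stars: *p<0.05, **p<0.01, ***p<0.001
significance_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Compare groups with t-tests or one-way ANOVA
#'
#' Two-sample or paired t-test for two groups, one-way ANOVA (with optional
#' Tukey post hoc contrasts) for more; group normality is screened with the
#' Shapiro-Wilk test and reported. Group summaries are mean +/- SD.
#'
#' @param values Named list of numeric vectors, one per group (exactly two
#'   for t designs).
#' @param design `"two-sample"`, `"paired"` or `"anova"`.
#' @param posthoc Run Tukey HSD contrasts after a significant ANOVA.
#' @return A list: `statistic`, `p_value`, `stars`, `design`,
#'   `group_means`, `group_sds`, `group_n`, `shapiro_p`, and `posthoc`
#'   (TukeyHSD table or `NULL`).
#' @export
compare_groups <- function(values,
                           design = c("two-sample", "paired", "anova"),
                           posthoc = FALSE) {
  design <- match.arg(design)
  if (!is.list(values) || length(values) < 2L)
    stop("compare_groups: need at least two groups")
  if (is.null(names(values)))
    names(values) <- paste0("group", seq_along(values))
  stats_of <- function(f) vapply(values, f, numeric(1L))
  shapiro_p <- vapply(values, function(g) {
    if (length(g) >= 3L && length(g) <= 5000L && stats::sd(g) > 0)
      stats::shapiro.test(g)$p.value else NA_real_
  }, numeric(1L))
  post <- NULL
  if (design %in% c("two-sample", "paired")) {
    if (length(values) != 2L)
      stop("compare_groups: t-test designs need exactly two groups")
    if (design == "paired" &&
        length(values[[1L]]) != length(values[[2L]]))
      stop("compare_groups: paired design requires equal-length groups")
    if (design == "paired" &&
        isTRUE(all.equal(values[[1L]], values[[2L]]))) {
      # identical pairs: zero differences, t-statistic defined as 0
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(values[[1L]], values[[2L]],
                          paired = design == "paired")
    }
    statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    df <- data.frame(value = unlist(values, use.names = FALSE),
                     group = factor(rep(names(values),
                                        lengths(values))))
    fit <- stats::aov(value ~ group, data = df)
    tab <- summary(fit)[[1L]]
    statistic <- tab[["F value"]][1L]; p <- tab[["Pr(>F)"]][1L]
    if (posthoc) post <- stats::TukeyHSD(fit)$group
  }
  list(statistic = statistic, p_value = p, stars = significance_stars(p),
       design = design, group_means = stats_of(mean),
       group_sds = stats_of(stats::sd), group_n = lengths(values),
       shapiro_p = shapiro_p, posthoc = post)
}
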