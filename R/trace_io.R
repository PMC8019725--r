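# Readers and writers for the plain-text interchange formats: TSV trace
# tables with a key-value comment header, CSV result tables, multi-page TIFF
# Z-stacks, and YAML-style run configuration.

#' Construct a reference Z-stack
#'
#' @param slices List of numeric matrices (equal dimensions), ordered along z.
#' @param increment Slice spacing in micrometres (> 0); the standard reference
#'   stack is 30 slices at 2 um.
#' @return An object of class `zstack`.
#' @export
zstack <- function(slices, increment = 2) {
  if (!length(slices)) stop("zstack: empty stack")
  dims <- vapply(slices, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("zstack: slices must share dimensions")
  if (increment <= 0) stop("zstack: increment must be > 0")
  structure(list(slices = slices, increment = increment,
                 n_slices = length(slices)),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$slices[[1L]])
  cat(sprintf("zstack: %d slices of %dx%d px, %g um increment\n",
              x$n_slices, d[1L], d[2L], x$increment))
  invisible(x)
}

#' Write a trace recording to a TSV file
#'
#' The file carries the recording metadata as `# key: value` comment lines
#' (sampling rate, ROI, condition, units, stimulus onsets) followed by a
#' tab-separated table with a `time_s` column and one column per scan line.
#'
#' @param rec A [trace_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(rec, path) {
  stopifnot(inherits(rec, "trace_recording"))
  header <- c(
    sprintf("# sampling_rate_hz: %.10g", rec$sampling_rate),
    sprintf("# roi: %s", rec$roi_label),
    sprintf("# condition: %s", rec$condition),
    sprintf("# units: %s", rec$units),
    sprintf("# stimulus_onsets_s: %s",
            paste(sprintf("%.9f", rec$stimulus_onsets), collapse = ",")))
  df <- data.frame(time_s = rec$times, rec$values)
  names(df) <- c("time_s", paste0("line", seq_len(ncol(rec$values))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trace recording from a TSV file
#'
#' Expects the format written by [write_trace_table()]: `# key: value` header
#' lines, then a tab-separated table whose first column is `time_s`. Metadata
#' missing from the header can be supplied through `schema`. The time grid is
#' validated (strictly increasing, uniform at the declared sampling rate);
#' malformed rows are reported by row number.
#'
#' @param path Input file path.
#' @param schema Optional named list overriding or supplying metadata:
#'   `sampling_rate_hz`, `roi`, `condition`, `units`, `stimulus_onsets_s`.
#' @return A [trace_recording()].
#' @export
read_trace_table <- function(path, schema = list()) {
  if (!file.exists(path)) stop("read_trace_table: file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  meta[names(schema)] <- schema
  if (is.null(meta$sampling_rate_hz))
    stop("read_trace_table: sampling rate missing from header and schema")
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop("read_trace_table: first column must be time_s")
  times <- df$time_s
  dup <- which(diff(times) == 0)
  if (length(dup))
    stop(sprintf("read_trace_table: duplicated timestamp at data row %d",
                 dup[1L] + 1L))
  onsets <- meta$stimulus_onsets_s
  onsets <- if (is.null(onsets) || !nzchar(onsets)) numeric()
    else as.numeric(strsplit(as.character(onsets), ",")[[1L]])
  trace_recording(
    times, as.matrix(df[setdiff(names(df), "time_s")]),
    sampling_rate = as.numeric(meta$sampling_rate_hz),
    roi_label = if (is.null(meta$roi)) "AIS" else meta$roi,
    stimulus_onsets = onsets,
    condition = if (is.null(meta$condition)) "vehicle" else meta$condition,
    units = if (is.null(meta$units)) "raw" else meta$units)
}

#' Write an analysis results table as CSV
#'
#' @param records A non-empty data.frame (e.g. a depression curve, intensity
#'   curve, or per-event fit table).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (is.null(records) || !nrow(as.data.frame(records)))
    stop("write_results_table: empty record set; no file written")
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Read an analysis results table written by [write_results_table()]
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a Z-stack to a multi-page TIFF
#'
#' Intensities are rescaled to `[0, 1]` for storage; the original peak is not
#' preserved (registration is scale-invariant).
#'
#' @param stack A [zstack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_zstack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  peak <- max(vapply(stack$slices, max, numeric(1L)))
  lo <- min(vapply(stack$slices, min, numeric(1L)))
  imgs <- lapply(stack$slices, function(s)
    if (peak > lo) (s - lo) / (peak - lo) else s * 0)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a Z-stack
#' @param path TIFF path.
#' @param increment Slice spacing in micrometres.
#' @return A [zstack()].
#' @export
read_zstack_tiff <- function(path, increment = 2) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  zstack(lapply(imgs, function(m) if (length(dim(m)) == 3L) m[, , 1L] else m),
         increment = increment)
}

# analysis defaults; the detection/fit constants mirror the standard pipeline
config_defaults <- function() {
  list(k_sd = 2, bin = 5, mse_max = 10, reference_lines = 150,
       sigma = 2, baseline_window = 0.5, max_shift = 5, discard_shift = 5,
       min_duration = 5, refractory = 0.2, window = 0.5, reference_db = 91.7)
}

#' Load a run configuration file
#'
#' Reads a plain-text YAML-style key-value file and merges it over the
#' analysis defaults (`k_sd = 2`, `bin = 5`, `mse_max = 10`,
#' `reference_lines = 150`, Gaussian `sigma = 2` samples, 0.5 s baseline and
#' peak windows, `reference_db = 91.7`). Unknown keys and type mismatches are
#' rejected.
#'
#' @param path Path to the config file; an empty file yields the full default
#'   set.
#' @return Named list of validated parameters.
#' @export
load_config <- function(path) {
  defaults <- config_defaults()
  user <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("load_config: file not found: ", path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("load_config: unknown key(s) %s; valid keys: %s",
                 paste(unknown, collapse = ", "),
                 paste(names(defaults), collapse = ", ")))
  for (k in names(user)) {
    if (!is.numeric(user[[k]]) || length(user[[k]]) != 1L)
      stop(sprintf("load_config: key '%s' must be a single number", k))
    defaults[[k]] <- user[[k]]
  }
  defaults
}
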