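#' Voltage trace container
#'
#' A uniformly sampled membrane-potential recording with its aligned stimulus
#' waveform. This is the substrate for all single-cell electrophysiology:
#' spike detection, action-potential feature extraction, passive properties,
#' and IPSP analysis on postsynaptic sweeps.
#'
#' @param time numeric vector of sample times in ms, uniformly spaced and
#'   strictly increasing.
#' @param voltage numeric vector of membrane potential in mV, same length as
#'   `time`.
#' @param stimulus numeric vector of injected current in pA, same length as
#'   `time`. Defaults to zeros.
#' @param cell_id,sweep_id identifiers carried in the metadata.
#' @param sampling_rate_khz sampling rate in kHz. If missing it is derived
#'   from `time`. Must lie in [1, 50] kHz.
#' @param temperature_c optional bath temperature in degrees Celsius.
#'
#' @return An object of class `voltage_trace`: a list with elements `time`,
#'   `voltage`, `stimulus` and `meta`.
#' @export
voltage_trace <- function(time, voltage, stimulus = NULL,
                          cell_id = "cell", sweep_id = "sweep",
                          sampling_rate_khz = NULL, temperature_c = NA_real_) {
  time <- as.numeric(time)
  voltage <- as.numeric(voltage)
  n <- length(time)
  if (n < 2L) stop("voltage_trace needs at least 2 samples")
  if (length(voltage) != n) stop("time and voltage lengths differ")
  if (is.null(stimulus)) stimulus <- numeric(n)
  stimulus <- as.numeric(stimulus)
  if (length(stimulus) != n) stop("time and stimulus lengths differ")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    stop("time must be uniformly sampled")
  }
  if (is.null(sampling_rate_khz)) sampling_rate_khz <- 1 / stats::median(dt)
  if (sampling_rate_khz < 1 || sampling_rate_khz > 50) {
    stop("sampling_rate_khz must be in [1, 50]")
  }
  structure(
    list(
      time = time, voltage = voltage, stimulus = stimulus,
      meta = list(cell_id = as.character(cell_id),
                  sweep_id = as.character(sweep_id),
                  sampling_rate_khz = sampling_rate_khz,
                  temperature_c = temperature_c)
    ),
    class = "voltage_trace"
  )
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf(
    "<voltage_trace> %s/%s: %d samples @ %.3g kHz, %.1f ms, V in [%.1f, %.1f] mV\n",
    x$meta$cell_id, x$meta$sweep_id, length(x$time),
    x$meta$sampling_rate_khz, diff(range(x$time)),
    min(x$voltage), max(x$voltage)
  ))
  invisible(x)
}

# sample interval in ms
trace_dt <- function(trace) {
  1 / trace$meta$sampling_rate_khz
}

#' Read a voltage trace from the columnar text format
#'
#' The columnar trace format is UTF-8 text with `#`-prefixed metadata header
#' lines of the form `# key: value` (required keys: `cell_id`, `sweep_id`,
#' `sampling_rate_khz`), followed by tab-separated columns
#' `time_ms voltage_mv stimulus_pa`.
#'
#' @param path path to a trace file.
#' @return A [voltage_trace()].
#' @export
read_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr & nzchar(trimws(lines))]
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    pos <- regexpr(":", kv, fixed = TRUE)
    if (pos < 0) stop("malformed header line: ", h)
    key <- trimws(substr(kv, 1, pos - 1))
    val <- trimws(substr(kv, pos + 1, nchar(kv)))
    meta[[key]] <- val
  }
  for (key in c("cell_id", "sweep_id", "sampling_rate_khz")) {
    if (is.null(meta[[key]])) stop("missing required header key: ", key)
  }
  if (length(body) == 0) stop("no data rows in ", path)
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 3L)) {
    bad <- which(nfield != 3L)[1]
    stop("ragged row (expected 3 tab-separated columns) at data line ", bad)
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric value in trace body of ", path)
  voltage_trace(
    time = m[, 1], voltage = m[, 2], stimulus = m[, 3],
    cell_id = meta$cell_id, sweep_id = meta$sweep_id,
    sampling_rate_khz = as.numeric(meta$sampling_rate_khz),
    temperature_c = if (is.null(meta$temperature_c)) NA_real_
                    else as.numeric(meta$temperature_c)
  )
}

#' Write a voltage trace to the columnar text format
#'
#' @param trace a [voltage_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "voltage_trace"))
  hdr <- c(
    sprintf("# cell_id: %s", trace$meta$cell_id),
    sprintf("# sweep_id: %s", trace$meta$sweep_id),
    sprintf("# sampling_rate_khz: %.12g", trace$meta$sampling_rate_khz)
  )
  if (!is.na(trace$meta$temperature_c)) {
    hdr <- c(hdr, sprintf("# temperature_c: %.12g", trace$meta$temperature_c))
  }
  body <- sprintf("%.12g\t%.12g\t%.12g",
                  trace$time, trace$voltage, trace$stimulus)
  writeLines(c(hdr, body), path)
  invisible(path)
}
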