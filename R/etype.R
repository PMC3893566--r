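#' Inter-spike-interval sequence of a spike train
#'
#' @param spikes a `spike_train` (or a numeric vector of peak times, ms).
#' @return Numeric vector of ISIs in ms, `ISI[i] = peak[i+1] - peak[i]`.
#' @export
isi_sequence <- function(spikes) {
  peaks <- if (inherits(spikes, "spike_train")) spikes$peak_times else
    as.numeric(spikes)
  if (length(peaks) < 3) {
    stop("insufficient data: at least 3 spikes are required for ISI analysis")
  }
  diff(peaks)
}

#' Ordinary least squares regression of ISI against AP sequence order
#'
#' The accommodation statistic behind the firing-type decision rules: ISIs are
#' regressed on their position in the train (1..n); the slope quantifies
#' accommodation and the root-mean-square of the residuals quantifies
#' goodness of fit.
#'
#' @param isis numeric vector of ISIs, ms (>= 2 values).
#' @return A list of class `isi_regression`: `slope` (ms per AP index),
#'   `intercept` (ms), `rms_error` (ms), `r` (Pearson correlation, 0 when the
#'   ISI sequence is constant) and `n_isi`.
#' @export
fit_isi_regression <- function(isis) {
  isis <- as.numeric(isis)
  n <- length(isis)
  if (n < 2) stop("at least 2 ISIs are required")
  x <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, x), isis)
  rms <- sqrt(mean(fit$residuals^2))
  r <- if (stats::sd(isis) == 0) 0 else stats::cor(x, isis)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 rms_error = rms, r = r, n_isi = n),
            class = "isi_regression")
}

#' @export
print.isi_regression <- function(x, ...) {
  cat(sprintf("<isi_regression> slope %.3f ms/AP, RMS %.2f ms, r %.3f (n = %d)\n",
              x$slope, x$rms_error, x$r, x$n_isi))
  invisible(x)
}

#' Silent periods within a spike train
#'
#' Returns all ISIs strictly greater than the gap threshold; the presence of
#' at least one such "silent period" of more than 100 ms is the stuttering
#' signature.
#'
#' @param isis numeric vector of ISIs, ms.
#' @param gap_threshold gap threshold, ms (strict inequality).
#' @return Numeric vector of the gap ISIs (possibly empty).
#' @export
detect_silent_periods <- function(isis, gap_threshold = 100) {
  isis <- as.numeric(isis)
  isis[isis > gap_threshold]
}

#' Detect a burst subtype at train onset
#'
#' `burst4`: the train opens with four rapid spikes, i.e. the mean of the
#' first three ISIs is strictly less than 25 ms. `doublet`: otherwise, the
#' train opens with a pair of APs whose ISI is at most 25 ms. `burst4` takes
#' precedence.
#'
#' @param isis numeric vector of ISIs, ms (>= 1 value).
#' @param burst_mean_ms mean-ISI bound for the four-spike burst (strict).
#' @param doublet_max_ms maximum first ISI for a doublet (inclusive).
#' @return `"burst4"`, `"doublet"` or `"none"`.
#' @export
detect_burst_subtype <- function(isis, burst_mean_ms = 25, doublet_max_ms = 25) {
  isis <- as.numeric(isis)
  if (length(isis) < 1) stop("at least 1 ISI required")
  if (length(isis) >= 3 && mean(isis[1:3]) < burst_mean_ms) return("burst4")
  if (isis[1] <= doublet_max_ms) return("doublet")
  "none"
}

#' Classify the firing pattern of a spike train
#'
#' Implements the regression-threshold decision tree over Petilla-style
#' layer-1 firing types:
#' \enumerate{
#'   \item RMS error of the ISI-vs-order regression greater than
#'     `rms_threshold`: stuttering (`cSTUT`) if the train contains at least
#'     one silent period longer than `gap_threshold`, otherwise irregular
#'     (`cIR`).
#'   \item RMS error at or below the threshold: a burst or doublet at train
#'     onset gives `bNAC`; otherwise slope at or above `slope_threshold`
#'     gives accommodating (`cAC`) and a smaller slope non-accommodating
#'     (`cNAC`).
#' }
#' The burst test precedes the slope test because bursting is defined
#' independently of accommodation. The regression is computed on all ISIs.
#'
#' @param spikes a `spike_train`, or numeric peak times in ms.
#' @param rms_threshold RMS-error threshold, ms.
#' @param slope_threshold accommodation slope threshold, ms per AP index.
#' @param gap_threshold silent-period threshold, ms.
#' @return A list of class `etype_label`: `label` in
#'   `{cAC, cNAC, bNAC, cSTUT, cIR, unclassified}`, `subtype` in
#'   `{burst4, doublet, none}` (non-`none` only for `bNAC`), and `evidence`
#'   (slope, rms_error, r, max_silent_gap, burst_isis, n_isi, reason).
#' @export
classify_etype <- function(spikes, rms_threshold = 30, slope_threshold = 1,
                           gap_threshold = 100) {
  peaks <- if (inherits(spikes, "spike_train")) spikes$peak_times else
    as.numeric(spikes)
  if (length(peaks) < 3) {
    return(structure(list(label = "unclassified", subtype = "none",
                          evidence = list(reason = "fewer than 3 spikes")),
                     class = "etype_label"))
  }
  isis <- isi_sequence(peaks)
  reg <- fit_isi_regression(isis)
  gaps <- detect_silent_periods(isis, gap_threshold)
  burst <- detect_burst_subtype(isis)
  if (reg$rms_error > rms_threshold) {
    label <- if (length(gaps) > 0) "cSTUT" else "cIR"
    subtype <- "none"
  } else if (burst != "none") {
    label <- "bNAC"
    subtype <- burst
  } else {
    label <- if (reg$slope >= slope_threshold) "cAC" else "cNAC"
    subtype <- "none"
  }
  structure(
    list(label = label, subtype = subtype,
         evidence = list(slope = reg$slope, rms_error = reg$rms_error,
                         r = reg$r,
                         max_silent_gap = if (length(gaps)) max(gaps) else NA_real_,
                         burst_isis = isis[seq_len(min(3, length(isis)))],
                         n_isi = reg$n_isi, reason = NA_character_)),
    class = "etype_label"
  )
}

#' @export
print.etype_label <- function(x, ...) {
  cat(sprintf("<etype_label> %s", x$label))
  if (x$subtype != "none") cat(sprintf(" (%s)", x$subtype))
  if (!is.null(x$evidence$slope)) {
    cat(sprintf(": slope %.2f, RMS %.2f", x$evidence$slope, x$evidence$rms_error))
    if (!is.na(x$evidence$max_silent_gap)) {
      cat(sprintf(", max gap %.0f ms", x$evidence$max_silent_gap))
    }
  }
  cat("\n")
  invisible(x)
}

#' Classify firing patterns for a directory or list of traces
#'
#' Convenience wrapper running spike detection and [classify_etype()] per
#' trace and returning one row per cell.
#'
#' @param traces a list of [voltage_trace()] objects, or a directory of
#'   columnar trace files.
#' @param ... passed to [classify_etype()].
#' @return A data.frame with `cell_id`, `label`, `subtype`, `slope`,
#'   `rms_error`, `max_gap`.
#' @export
classify_etype_batch <- function(traces, ...) {
  if (is.character(traces)) {
    files <- list.files(traces, full.names = TRUE)
    traces <- lapply(files, read_trace)
  }
  rows <- lapply(traces, function(tr) {
    lab <- classify_etype(detect_spikes(tr), ...)
    data.frame(cell_id = tr$meta$cell_id, label = lab$label,
               subtype = lab$subtype,
               slope = if (is.null(lab$evidence$slope)) NA_real_ else lab$evidence$slope,
               rms_error = if (is.null(lab$evidence$rms_error)) NA_real_ else lab$evidence$rms_error,
               max_gap = if (is.null(lab$evidence$max_silent_gap)) NA_real_ else lab$evidence$max_silent_gap,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
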