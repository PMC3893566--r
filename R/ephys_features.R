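#' Detect action potentials in a voltage trace
#'
#' A spike is a suprathreshold excursion whose peak exceeds `min_peak`; its
#' threshold time is the first sample of the contiguous run of dV/dt >=
#' `dvdt_threshold` preceding the peak. Peaks closer than `refractory` are
#' merged (the higher peak is kept).
#'
#' @param trace a [voltage_trace()].
#' @param dvdt_threshold voltage slope threshold, mV/ms.
#' @param min_peak minimum peak voltage, mV.
#' @param refractory minimum peak separation, ms.
#' @return An object of class `spike_train`: list with sorted `peak_times`,
#'   `threshold_times` (ms), `peak_idx`, `threshold_idx` and `n_spikes`.
#'   An empty train is allowed.
#' @export
detect_spikes <- function(trace, dvdt_threshold = 20, min_peak = -10,
                          refractory = 2) {
  stopifnot(inherits(trace, "voltage_trace"))
  v <- trace$voltage
  t <- trace$time
  dt <- trace_dt(trace)
  n <- length(v)
  dvdt <- c(diff(v) / dt, 0)
  fast <- dvdt >= dvdt_threshold

  # candidate peaks: local maxima above min_peak preceded by a fast upstroke
  is_peak <- c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] &
                 v[2:(n - 1)] > v[3:n], FALSE)
  cand <- which(is_peak & v > min_peak)
  keep <- integer(0)
  thr_idx <- integer(0)
  for (p in cand) {
    # walk back to the start of the contiguous fast-upstroke run
    i <- p - 1L
    while (i >= 1L && !fast[i] && (t[p] - t[i]) <= 5) i <- i - 1L
    if (i < 1L || !fast[i]) next  # no upstroke: not a spike
    j <- i
    while (j > 1L && fast[j - 1L]) j <- j - 1L
    keep <- c(keep, p)
    thr_idx <- c(thr_idx, j)
  }
  # merge peaks within the refractory period, keeping the higher one
  if (length(keep) > 1L) {
    ord <- order(t[keep])
    keep <- keep[ord]; thr_idx <- thr_idx[ord]
    out_p <- keep[1]; out_t <- thr_idx[1]
    for (k in 2:length(keep)) {
      last <- length(out_p)
      if (t[keep[k]] - t[out_p[last]] < refractory) {
        if (v[keep[k]] > v[out_p[last]]) {
          out_p[last] <- keep[k]; out_t[last] <- thr_idx[k]
        }
      } else {
        out_p <- c(out_p, keep[k]); out_t <- c(out_t, thr_idx[k])
      }
    }
    keep <- out_p; thr_idx <- out_t
  }
  structure(
    list(peak_times = t[keep], threshold_times = t[thr_idx],
         peak_idx = keep, threshold_idx = thr_idx,
         n_spikes = length(keep)),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes", x$n_spikes))
  if (x$n_spikes > 0) {
    cat(sprintf(", t in [%.1f, %.1f] ms", min(x$peak_times), max(x$peak_times)))
  }
  cat("\n")
  invisible(x)
}

# linear interpolation of the time where v crosses `level` between samples
# i and i+1 (assumes a sign change of v - level across the pair)
cross_time <- function(t, v, i, level) {
  if (v[i + 1] == v[i]) return(t[i])
  t[i] + (level - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
}

#' Extract per-spike action-potential features
#'
#' Conventions: amplitude is measured threshold-to-peak; rise and fall times
#' between the 20% and 80% amplitude crossings on each flank (mirroring the
#' 20-80% kinetic convention used for synaptic potentials); duration is the
#' full width at the threshold voltage level; half-width the full width at 50%
#' amplitude; the fast AHP is threshold voltage minus the post-spike minimum
#' within `ahp_window`. Features that cannot be measured (truncated spike,
#' no minimum before the next spike) are returned as `NA` rather than
#' fabricated.
#'
#' @param trace a [voltage_trace()].
#' @param spikes a `spike_train` from [detect_spikes()].
#' @param index 1-based ordinal of the spike in the train.
#' @param ahp_window window after the peak searched for the AHP minimum, ms.
#' @param frac_lo,frac_hi amplitude fractions for the kinetic measurements.
#' @return A list of class `ap_features` with elements `amplitude`,
#'   `duration`, `half_width`, `rise_time`, `fall_time`, `ahp_time`,
#'   `rise_rate`, `fall_rate`, `fast_ahp`, `threshold_voltage`, `peak_voltage`.
#' @export
extract_ap_features <- function(trace, spikes, index = 1, ahp_window = 30,
                                frac_lo = 0.2, frac_hi = 0.8) {
  stopifnot(inherits(spikes, "spike_train"))
  if (index > spikes$n_spikes) stop("index exceeds spike count")
  v <- trace$voltage; t <- trace$time
  p <- spikes$peak_idx[index]
  th <- spikes$threshold_idx[index]
  v_thr <- v[th]; v_peak <- v[p]
  amplitude <- v_peak - v_thr
  lo <- v_thr + frac_lo * amplitude
  hi <- v_thr + frac_hi * amplitude
  half <- v_thr + 0.5 * amplitude

  end_idx <- if (index < spikes$n_spikes) {
    spikes$threshold_idx[index + 1] } else length(v)

  rise_lo <- rise_hi <- fall_hi <- fall_lo <- dur_up <- dur_dn <- half_up <- half_dn <- NA_real_
  # rising flank: search th..p
  for (i in th:(p - 1)) {
    if (is.na(rise_lo) && v[i] <= lo && v[i + 1] > lo)
      rise_lo <- cross_time(t, v, i, lo)
    if (is.na(half_up) && v[i] <= half && v[i + 1] > half)
      half_up <- cross_time(t, v, i, half)
    if (is.na(rise_hi) && v[i] <= hi && v[i + 1] > hi)
      rise_hi <- cross_time(t, v, i, hi)
  }
  dur_up <- t[th]
  # falling flank: search p..end
  i <- p
  while (i < end_idx) {
    if (is.na(fall_hi) && v[i] >= hi && v[i + 1] < hi)
      fall_hi <- cross_time(t, v, i, hi)
    if (is.na(half_dn) && v[i] >= half && v[i + 1] < half)
      half_dn <- cross_time(t, v, i, half)
    if (is.na(fall_lo) && v[i] >= lo && v[i + 1] < lo)
      fall_lo <- cross_time(t, v, i, lo)
    if (is.na(dur_dn) && v[i] >= v_thr && v[i + 1] < v_thr)
      dur_dn <- cross_time(t, v, i, v_thr)
    if (!is.na(fall_lo) && !is.na(dur_dn)) break
    i <- i + 1L
  }
  # AHP: minimum after the spike returns below threshold, before next spike
  ahp_time <- fast_ahp <- NA_real_
  if (!is.na(dur_dn)) {
    win <- which(t > dur_dn & t <= min(t[p] + ahp_window, t[end_idx]))
    if (length(win) > 2) {
      mi <- win[which.min(v[win])]
      if (mi < max(win)) {  # a true minimum, not a truncation
        ahp_time <- t[mi] - t[p]
        fast_ahp <- v_thr - v[mi]
      }
    }
  }
  rise_time <- if (!is.na(rise_lo) && !is.na(rise_hi)) rise_hi - rise_lo else NA_real_
  fall_time <- if (!is.na(fall_hi) && !is.na(fall_lo)) fall_lo - fall_hi else NA_real_
  duration <- if (!is.na(dur_dn)) dur_dn - dur_up else NA_real_
  half_width <- if (!is.na(half_up) && !is.na(half_dn)) half_dn - half_up else NA_real_
  frac_span <- (frac_hi - frac_lo) * amplitude
  structure(
    list(amplitude = amplitude, duration = duration, half_width = half_width,
         rise_time = rise_time, fall_time = fall_time, ahp_time = ahp_time,
         rise_rate = if (!is.na(rise_time) && rise_time > 0) frac_span / rise_time else NA_real_,
         fall_rate = if (!is.na(fall_time) && fall_time > 0) frac_span / fall_time else NA_real_,
         fast_ahp = fast_ahp, threshold_voltage = v_thr, peak_voltage = v_peak),
    class = "ap_features"
  )
}

#' @export
print.ap_features <- function(x, ...) {
  cat(sprintf(
    "<ap_features> amp %.1f mV, half-width %.2f ms, rise %.2f ms, fall %.2f ms, fAHP %.1f mV\n",
    x$amplitude, x$half_width, x$rise_time, x$fall_time, x$fast_ahp))
  invisible(x)
}

#' Extract passive membrane properties
#'
#' Input resistances from a hyperpolarizing current step (peak and
#' steady-state deflection divided by step current; steady state is the mean
#' over the last 20% of the step) and the membrane time constant from a
#' single-exponential fit to the decay after a brief "delta" pulse.
#'
#' @param trace_hyperpol a [voltage_trace()] containing a hyperpolarizing
#'   square step in its stimulus channel.
#' @param trace_delta optional trace with a brief pulse; the decay after the
#'   pulse is fit with `v = v0 + a * exp(-t / tau)`.
#' @return A list of class `passive_features`: `r_in_peak`, `r_in_ss` (MOhm),
#'   `tau_delta` (ms, `NA` if no delta trace), `baseline_mv`, `step_pa`.
#' @export
extract_passive <- function(trace_hyperpol, trace_delta = NULL) {
  tr <- trace_hyperpol
  on_idx <- which(tr$stimulus != 0)
  if (length(on_idx) == 0) stop("no current step in stimulus channel")
  i_step <- stats::median(tr$stimulus[on_idx])
  if (i_step == 0) stop("zero-amplitude step")
  t_on <- tr$time[min(on_idx)]
  t_off <- tr$time[max(on_idx)]
  pre <- tr$voltage[tr$time < t_on]
  if (length(pre) < 2) stop("no pre-step baseline")
  v0 <- mean(pre)
  step_v <- tr$voltage[on_idx]
  # deflection sign follows the current sign
  peak_defl <- if (i_step < 0) min(step_v) - v0 else max(step_v) - v0
  ss_win <- on_idx[tr$time[on_idx] >= t_off - 0.2 * (t_off - t_on)]
  ss_defl <- mean(tr$voltage[ss_win]) - v0
  # pA * MOhm = mV * 1000 => MOhm = 1000 * mV / pA
  r_in_peak <- 1000 * peak_defl / i_step
  r_in_ss <- 1000 * ss_defl / i_step

  tau_delta <- NA_real_
  if (!is.null(trace_delta)) {
    td <- trace_delta
    pulse <- which(td$stimulus != 0)
    if (length(pulse) == 0) stop("no pulse in delta trace")
    start <- max(pulse) + 1L
    idx <- start:length(td$time)
    tt <- td$time[idx] - td$time[start]
    vv <- td$voltage[idx]
    base <- mean(td$voltage[td$time < td$time[min(pulse)]])
    a0 <- vv[1] - base
    fit <- try(stats::nls(vv ~ v0f + af * exp(-tt / tauf),
                          start = list(v0f = base, af = a0, tauf = 10),
                          control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      stop("delta-pulse exponential fit did not converge: ",
           attr(fit, "condition")$message)
    }
    tau_delta <- stats::coef(fit)[["tauf"]]
  }
  structure(list(r_in_peak = r_in_peak, r_in_ss = r_in_ss,
                 tau_delta = tau_delta, baseline_mv = v0, step_pa = i_step),
            class = "passive_features")
}

#' Rheobase from a family of current steps
#'
#' Returns the smallest tested step amplitude that elicits at least one
#' action potential ("minimum current to threshold"). The calibration
#' convention is a square pulse whose amplitude is scaled until it produces
#' a spike.
#'
#' @param sweep_family list of [voltage_trace()] sweeps, each with its step in
#'   the stimulus channel (amplitude read from the stimulus, or from
#'   `meta$step_pa` if present).
#' @param ... passed to [detect_spikes()].
#' @return Rheobase in pA.
#' @export
calibrate_rheobase <- function(sweep_family, ...) {
  amps <- vapply(sweep_family, function(tr) {
    if (!is.null(tr$meta$step_pa)) return(tr$meta$step_pa)
    s <- tr$stimulus[tr$stimulus != 0]
    if (length(s) == 0) 0 else stats::median(s)
  }, numeric(1))
  spiking <- vapply(sweep_family, function(tr) {
    detect_spikes(tr, ...)$n_spikes >= 1L
  }, logical(1))
  if (!any(spiking)) stop("no sweep in the family elicited an action potential")
  min(amps[spiking])
}
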