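#' Action-potential waveform template
#'
#' Analytic spike waveform used by the synthetic-trace generator: a
#' difference-of-exponentials upstroke/downstroke whose full width at half
#' maximum is calibrated to `half_width`, followed by a difference-of-
#' exponentials after-hyperpolarization of depth `ahp_depth`. The waveform is
#' a deviation from the local baseline, starting at 0 at `t = 0` (spike
#' onset). Being a closed-form function of time, 20-80% crossing times can be
#' computed by root finding and used as an independent oracle for the
#' sample-based feature extractor.
#'
#' @param t numeric vector of times in ms since spike onset (values < 0 give 0).
#' @param amplitude spike height above onset baseline, mV.
#' @param half_width full width at half maximum of the spike, ms.
#' @param ahp_depth after-hyperpolarization depth below onset baseline, mV.
#' @param tau_ahp recovery time constant of the AHP, ms.
#' @return numeric vector of voltage deviations (mV).
#' @export
ap_template <- function(t, amplitude = 80, half_width = 2, ahp_depth = 12,
                        tau_ahp = 15) {
  sh <- ap_template_shape(amplitude, half_width, ahp_depth, tau_ahp)
  ap_template_eval(t, sh)
}

# Precompute template constants; generator calls this once per cell.
ap_template_shape <- function(amplitude, half_width, ahp_depth, tau_ahp) {
  tau_r <- half_width / 4
  # calibrate the fall time constant so the biexponential FWHM = half_width
  fwhm_of <- function(tau_f) {
    tp <- log(tau_f / tau_r) * tau_f * tau_r / (tau_f - tau_r)
    peak <- exp(-tp / tau_f) - exp(-tp / tau_r)
    half <- peak / 2
    f <- function(t) exp(-t / tau_f) - exp(-t / tau_r) - half
    t1 <- stats::uniroot(f, c(1e-9, tp))$root
    t2 <- stats::uniroot(f, c(tp, tp + 20 * tau_f))$root
    t2 - t1
  }
  g <- function(tau_f) fwhm_of(tau_f) - half_width
  tau_f <- stats::uniroot(g, c(tau_r * 1.05, half_width * 20))$root
  tp <- log(tau_f / tau_r) * tau_f * tau_r / (tau_f - tau_r)
  norm <- exp(-tp / tau_f) - exp(-tp / tau_r)
  # AHP starts where the spike tail has decayed to ~2% of amplitude
  t_ahp0 <- tau_f * log(1 / (0.02 * norm))
  tau_ahp_r <- half_width
  list(amplitude = amplitude, tau_r = tau_r, tau_f = tau_f, t_peak = tp,
       norm = norm, ahp_depth = ahp_depth, tau_ahp = tau_ahp,
       tau_ahp_r = tau_ahp_r, t_ahp0 = t_ahp0,
       duration = t_ahp0)
}

ap_template_eval <- function(t, sh) {
  v <- numeric(length(t))
  up <- t >= 0
  tt <- t[up]
  spike <- sh$amplitude * (exp(-tt / sh$tau_f) - exp(-tt / sh$tau_r)) / sh$norm
  ta <- tt - sh$t_ahp0
  ahp <- ifelse(ta > 0, -sh$ahp_depth * ahp_unit(ta, sh$tau_ahp_r, sh$tau_ahp), 0)
  v[up] <- spike + ahp
  v
}

# unit-peak difference of exponentials, rise tau_r < decay tau_d
ahp_unit <- function(t, tau_r, tau_d) {
  tp <- log(tau_d / tau_r) * tau_d * tau_r / (tau_d - tau_r)
  norm <- exp(-tp / tau_d) - exp(-tp / tau_r)
  (exp(-t / tau_d) - exp(-t / tau_r)) / norm
}

#' Specification for a synthetic firing-pattern response
#'
#' Describes the inter-spike-interval (ISI) statistics of one of the five
#' layer-1 firing types (with the bursting type split into its two subtypes),
#' plus the spike waveform and sampling parameters. The per-type defaults in
#' [etype_gen_defaults()] are the study conditions used throughout the tests.
#'
#' @param etype one of `"cAC"`, `"cNAC"`, `"bNAC_burst"`, `"bNAC_doublet"`,
#'   `"cSTUT"`, `"cIR"`.
#' @param base_isi baseline inter-spike interval, ms.
#' @param isi_slope linear ISI accommodation per AP index, ms.
#' @param isi_noise_sd Gaussian ISI jitter SD, ms.
#' @param n_spikes number of action potentials (>= 2).
#' @param silent_period duration of stutter pauses, ms; must be > 100 for
#'   `cSTUT` and is ignored otherwise.
#' @param n_silent number of silent periods inserted (`cSTUT` only).
#' @param ap_shape list with `amplitude` (mV), `half_width` (ms),
#'   `ahp_depth` (mV), `threshold` (mV).
#' @param sampling_rate kHz, in [5, 10].
#' @param sweep_ms total sweep duration, ms.
#' @param stim_onset stimulus step onset, ms.
#' @param stim_pa stimulus step amplitude, pA.
#' @param baseline resting potential, mV.
#' @param seed integer seed making the generated trace deterministic.
#' @return An object of class `ephys_gen_spec`.
#' @export
ephys_gen_spec <- function(etype, base_isi = 30, isi_slope = 0,
                           isi_noise_sd = 0, n_spikes = 15,
                           silent_period = 150, n_silent = 2,
                           ap_shape = list(amplitude = 80, half_width = 2,
                                           ahp_depth = 12, threshold = -45),
                           sampling_rate = 10, sweep_ms = 2000,
                           stim_onset = 100, stim_pa = 100,
                           baseline = -65, seed = 1) {
  etype <- match.arg(etype, c("cAC", "cNAC", "bNAC_burst", "bNAC_doublet",
                              "cSTUT", "cIR"))
  if (base_isi <= 0) stop("base_isi must be > 0")
  if (n_spikes < 2) stop("n_spikes must be >= 2")
  if (sampling_rate < 5 || sampling_rate > 10) {
    stop("sampling_rate must be in [5, 10] kHz")
  }
  if (etype == "cSTUT" && silent_period <= 100) {
    stop("cSTUT requires silent_period > 100 ms")
  }
  structure(
    list(etype = etype, base_isi = base_isi, isi_slope = isi_slope,
         isi_noise_sd = isi_noise_sd, n_spikes = as.integer(n_spikes),
         silent_period = silent_period, n_silent = as.integer(n_silent),
         ap_shape = ap_shape, sampling_rate = sampling_rate,
         sweep_ms = sweep_ms, stim_onset = stim_onset, stim_pa = stim_pa,
         baseline = baseline, seed = as.integer(seed)),
    class = "ephys_gen_spec"
  )
}

#' Per-type generator defaults for the five firing patterns
#'
#' Returns the default [ephys_gen_spec()] for a firing type, at the ISI
#' statistics the classifier rules are built around: accommodating cells get a
#' clear positive ISI slope and small jitter; non-accommodating cells a flat
#' ISI sequence; bursting cells an initial four-spike burst (mean ISI < 25 ms)
#' or a doublet (first ISI <= 25 ms); stuttering cells silent periods near the
#' reported 193 ms mean over ~38 ms spiking ISIs; irregular cells a strongly
#' bimodal short/long ISI mixture with all gaps below 100 ms.
#'
#' @param etype firing type label (see [ephys_gen_spec()]).
#' @param seed integer seed.
#' @return An `ephys_gen_spec`.
#' @export
etype_gen_defaults <- function(etype, seed = 1) {
  switch(match.arg(etype, c("cAC", "cNAC", "bNAC_burst", "bNAC_doublet",
                            "cSTUT", "cIR")),
    cAC = ephys_gen_spec("cAC", base_isi = 30, isi_slope = 2.5,
                         isi_noise_sd = 2, n_spikes = 15, seed = seed),
    cNAC = ephys_gen_spec("cNAC", base_isi = 35, isi_slope = 0.1,
                          isi_noise_sd = 2.5, n_spikes = 18, seed = seed),
    bNAC_burst = ephys_gen_spec("bNAC_burst", base_isi = 40, isi_slope = 0.2,
                                isi_noise_sd = 2.5, n_spikes = 15, seed = seed),
    bNAC_doublet = ephys_gen_spec("bNAC_doublet", base_isi = 40,
                                  isi_slope = 0.2, isi_noise_sd = 2.5,
                                  n_spikes = 15, seed = seed),
    cSTUT = ephys_gen_spec("cSTUT", base_isi = 38, isi_slope = 0,
                           isi_noise_sd = 6, n_spikes = 18,
                           silent_period = 190, n_silent = 2, seed = seed),
    cIR = ephys_gen_spec("cIR", base_isi = 50, isi_slope = 0,
                         isi_noise_sd = 0, n_spikes = 18, seed = seed)
  )
}

# Draw the ground-truth ISI sequence for a spec (seeded by the caller).
draw_isi_sequence <- function(spec) {
  n_isi <- spec$n_spikes - 1L
  k <- seq_len(n_isi)
  base <- spec$base_isi + spec$isi_slope * (k - 1)
  isis <- switch(spec$etype,
    cAC = ,
    cNAC = base + stats::rnorm(n_isi, 0, spec$isi_noise_sd),
    bNAC_burst = {
      if (n_isi < 4) stop("bNAC_burst needs at least 5 spikes")
      y <- base + stats::rnorm(n_isi, 0, spec$isi_noise_sd)
      y[1:3] <- c(8, 9, 10) + stats::rnorm(3, 0, 1)
      y
    },
    bNAC_doublet = {
      y <- base + stats::rnorm(n_isi, 0, spec$isi_noise_sd)
      y[1] <- 15 + stats::rnorm(1, 0, 2)
      y
    },
    cSTUT = {
      y <- base + stats::rnorm(n_isi, 0, spec$isi_noise_sd)
      n_gap <- min(spec$n_silent, n_isi - 1L)
      at <- sample(2:n_isi, n_gap)
      y[at] <- spec$silent_period + stats::rnorm(n_gap, 0, 15)
      y
    },
    cIR = {
      short <- stats::runif(n_isi, 8, 18)
      long <- stats::runif(n_isi, 80, 98)
      pick <- stats::runif(n_isi) < 0.5
      y <- ifelse(pick, short, long)
      # an irregular train should not open with a doublet-like pair
      if (y[1] <= 25) y[1] <- stats::runif(1, 80, 98)
      y
    }
  )
  pmax(isis, 4)  # keep spikes resolvable
}

#' Generate a synthetic spike response trace
#'
#' Realizes the spec's ISI structure as spike times, renders each spike with
#' the analytic [ap_template()] on top of a square current step, and returns a
#' [voltage_trace()] with the ground truth attached. Deterministic for a fixed
#' spec (the spec's `seed` is used internally and the RNG state of the caller
#' is restored).
#'
#' @param spec an [ephys_gen_spec()].
#' @return A `voltage_trace` with attribute `ground_truth`: a list with the
#'   drawn `isis`, `spike_onsets` (ms), and the spec.
#' @export
generate_spike_response <- function(spec) {
  stopifnot(inherits(spec, "ephys_gen_spec"))
  gt <- with_seed(spec$seed, {
    isis <- draw_isi_sequence(spec)
    list(isis = isis, spike_onsets = spec$stim_onset + 10 + cumsum(c(0, isis)))
  })
  total_spike_span <- max(gt$spike_onsets) + 20
  if (total_spike_span > spec$sweep_ms) {
    stop("infeasible spec: spike train (", round(total_spike_span),
         " ms) exceeds sweep of ", spec$sweep_ms, " ms")
  }
  dt <- 1 / spec$sampling_rate
  time <- seq(0, spec$sweep_ms - dt, by = dt)
  v <- rep(spec$baseline, length(time))
  sh <- ap_template_shape(spec$ap_shape$amplitude, spec$ap_shape$half_width,
                          spec$ap_shape$ahp_depth, 15)
  for (on in gt$spike_onsets) {
    idx <- which(time >= on & time <= on + 8 * sh$tau_ahp + sh$t_ahp0)
    v[idx] <- v[idx] + ap_template_eval(time[idx] - on, sh)
  }
  stim_end <- max(gt$spike_onsets) + 50
  stim <- ifelse(time >= spec$stim_onset & time < stim_end, spec$stim_pa, 0)
  tr <- voltage_trace(time, v, stim,
                      cell_id = paste0(spec$etype, "_s", spec$seed),
                      sweep_id = "step", sampling_rate_khz = spec$sampling_rate)
  attr(tr, "ground_truth") <- c(gt, list(spec = spec))
  tr
}

#' Generate a family of current-step sweeps with a built-in rheobase
#'
#' Produces one sweep per requested step amplitude: sweeps below the cell's
#' rheobase show a passive RC charging response, sweeps at or above it show a
#' spike train. Used to exercise rheobase calibration with known ground truth.
#'
#' @param rheobase_pa smallest amplitude that elicits spiking, pA.
#' @param amplitudes_pa vector of tested step amplitudes, pA.
#' @param r_in_mohm input resistance of the passive response, MOhm.
#' @param tau_ms membrane time constant, ms.
#' @param spec an [ephys_gen_spec()] used to render suprathreshold sweeps.
#' @return A list of `voltage_trace` sweeps, with attribute `rheobase_pa`.
#' @export
generate_step_family <- function(rheobase_pa, amplitudes_pa,
                                 r_in_mohm = 300, tau_ms = 18,
                                 spec = etype_gen_defaults("cNAC")) {
  sweeps <- lapply(seq_along(amplitudes_pa), function(i) {
    amp <- amplitudes_pa[i]
    if (amp >= rheobase_pa) {
      sp <- spec
      sp$stim_pa <- amp
      sp$seed <- spec$seed + i
      tr <- generate_spike_response(sp)
    } else {
      dt <- 1 / spec$sampling_rate
      time <- seq(0, spec$sweep_ms - dt, by = dt)
      on <- spec$stim_onset
      off <- spec$sweep_ms - 400
      # RC step response: deflection in mV = pA * MOhm / 1000
      defl <- amp * r_in_mohm / 1000
      v <- spec$baseline +
        defl * (1 - exp(-(time - on) / tau_ms)) * (time >= on & time < off) +
        defl * (1 - exp(-(off - on) / tau_ms)) *
          exp(-(time - off) / tau_ms) * (time >= off)
      stim <- ifelse(time >= on & time < off, amp, 0)
      tr <- voltage_trace(time, v, stim,
                          cell_id = spec$etype, sweep_id = paste0("amp", amp),
                          sampling_rate_khz = spec$sampling_rate)
    }
    tr$meta$step_pa <- amp
    tr
  })
  attr(sweeps, "rheobase_pa") <- rheobase_pa
  sweeps
}

# Evaluate an expression with a local, restored RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
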