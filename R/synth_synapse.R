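#' Specification for a synthetic synaptic connection
#'
#' Generative parameters of an inhibitory connection between two layer-1
#' interneurons. The fast component is an ionotropic (GABA-A-like)
#' biexponential IPSP triggered by every presynaptic spike. The slow
#' component is a metabotropic (GABA-B-like) cascade: each spike feeds a
#' decaying transmitter pool which gates a slow conductance through a
#' cooperative Hill function with `n_binding_sites` G-protein binding sites,
#' so that single spikes produce a negligible response while trains at or
#' above `min_drive_freq` activate it, with a sigmoidal rising phase, an
#' onset delay and a slow multi-exponential decay. Repetitions of the whole
#' protocol are scaled geometrically by `(1 - rundown_rate)^k` (whole-cell
#' rundown; perforated-patch specs use `rundown_rate = 0`).
#'
#' @param receptor `"GABA_A"`, `"GABA_B"` or `"GABA_AB"`.
#' @param gA_amp fast-component amplitude, mV (per single AP).
#' @param tau_rise_A,tau_decay_A fast-component kinetics, ms
#'   (rise < decay).
#' @param gB_amp slow-component amplitude scale, mV.
#' @param gB_onset_delay cascade onset delay, ms (10-20).
#' @param n_binding_sites Hill coefficient of the G-protein gate.
#' @param min_drive_freq minimum presynaptic frequency activating the slow
#'   component, Hz.
#' @param tau_pool transmitter-pool decay time constant, ms.
#' @param tau_rise_B,tau_decay_B slow-component kernel kinetics, ms.
#' @param rundown_rate fractional amplitude loss per repetition, in [0, 1).
#' @param noise_sd additive Gaussian noise SD per sample, mV.
#' @param n_repetitions number of sweeps.
#' @param holding_potential postsynaptic holding potential, mV.
#' @param patch_mode `"whole_cell"` or `"perforated"` (perforated forces
#'   `rundown_rate = 0`).
#' @param inter_stimulus_interval_s protocol inter-stimulus interval, s
#'   (one of 30, 60, 90, 120).
#' @param sampling_rate kHz.
#' @param seed integer seed.
#' @return An object of class `synapse_gen_spec`.
#' @export
synapse_gen_spec <- function(receptor, gA_amp = 2, tau_rise_A = 5,
                             tau_decay_A = 40, gB_amp = 4,
                             gB_onset_delay = 15, n_binding_sites = 4,
                             min_drive_freq = 40, tau_pool = 80,
                             tau_rise_B = 80, tau_decay_B = 300,
                             rundown_rate = 0.1, noise_sd = 0.05,
                             n_repetitions = 5, holding_potential = -57,
                             patch_mode = c("whole_cell", "perforated"),
                             inter_stimulus_interval_s = 30,
                             sampling_rate = 10, seed = 1) {
  receptor <- match.arg(receptor, c("GABA_A", "GABA_B", "GABA_AB"))
  patch_mode <- match.arg(patch_mode)
  if (tau_rise_A >= tau_decay_A) stop("tau_rise_A must be < tau_decay_A")
  if (rundown_rate < 0 || rundown_rate >= 1) {
    stop("rundown_rate must be in [0, 1)")
  }
  if (!inter_stimulus_interval_s %in% c(30, 60, 90, 120)) {
    stop("inter_stimulus_interval_s must be one of 30, 60, 90, 120")
  }
  if (patch_mode == "perforated") rundown_rate <- 0
  structure(
    list(receptor = receptor, gA_amp = gA_amp, tau_rise_A = tau_rise_A,
         tau_decay_A = tau_decay_A, gB_amp = gB_amp,
         gB_onset_delay = gB_onset_delay,
         n_binding_sites = n_binding_sites, min_drive_freq = min_drive_freq,
         tau_pool = tau_pool, tau_rise_B = tau_rise_B,
         tau_decay_B = tau_decay_B, rundown_rate = rundown_rate,
         noise_sd = noise_sd, n_repetitions = as.integer(n_repetitions),
         holding_potential = holding_potential, patch_mode = patch_mode,
         inter_stimulus_interval_s = inter_stimulus_interval_s,
         sampling_rate = sampling_rate, seed = as.integer(seed)),
    class = "synapse_gen_spec"
  )
}

# unit-peak biexponential kernel evaluated on a time grid (t >= 0)
biexp_kernel <- function(t, tau_rise, tau_decay) {
  tp <- log(tau_decay / tau_rise) * tau_decay * tau_rise /
    (tau_decay - tau_rise)
  norm <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise)) / norm
  out
}

# Slow-cascade gate: transmitter pool with per-spike unit increments and
# exponential decay, passed through a cooperative Hill function whose
# half-activation tracks the pool level reached by a train at min_drive_freq.
gabab_gate <- function(time, pre_spikes, spec) {
  dt <- time[2] - time[1]
  pool <- numeric(length(time))
  decay <- exp(-dt / spec$tau_pool)
  spike_idx <- findInterval(pre_spikes, time)
  lev <- 0
  j <- 1
  for (i in seq_along(time)) {
    lev <- lev * decay
    while (j <= length(spike_idx) && spike_idx[j] == i) {
      lev <- lev + 1
      j <- j + 1
    }
    pool[i] <- lev
  }
  # pool level a sustained train at min_drive_freq asymptotes to
  isi_ms <- 1000 / spec$min_drive_freq
  k_half <- 0.9 / (1 - exp(-isi_ms / spec$tau_pool))
  h <- pool^spec$n_binding_sites
  h / (h + k_half^spec$n_binding_sites)
}

#' Generate a synthetic paired recording
#'
#' Renders `n_repetitions` postsynaptic sweeps in response to the given
#' presynaptic spike times, with fast and/or slow IPSP components according
#' to the receptor class of the spec, geometric amplitude rundown across
#' repetitions, and seeded Gaussian noise.
#'
#' @param spec a [synapse_gen_spec()].
#' @param pre_spikes sorted presynaptic spike times, ms (non-empty).
#' @param sweep_ms sweep duration, ms; defaults to the last spike + 1500 ms
#'   so the slow component is captured.
#' @return An object of class `paired_recording`: list with
#'   `pre_spike_times`, `post_sweeps` (list of [voltage_trace()]),
#'   `holding_potential`, `stim_frequency` (Hz, from the median pre ISI),
#'   `inter_stimulus_interval_s`, `patch_mode` and `ground_truth`.
#' @export
generate_paired_recording <- function(spec, pre_spikes, sweep_ms = NULL) {
  stopifnot(inherits(spec, "synapse_gen_spec"))
  pre_spikes <- as.numeric(pre_spikes)
  if (length(pre_spikes) == 0) stop("pre_spikes must be non-empty")
  if (is.unsorted(pre_spikes)) stop("pre_spikes must be sorted")
  if (is.null(sweep_ms)) sweep_ms <- max(pre_spikes) + 1500
  dt <- 1 / spec$sampling_rate
  time <- seq(0, sweep_ms - dt, by = dt)

  fast <- numeric(length(time))
  if (spec$receptor %in% c("GABA_A", "GABA_AB")) {
    for (s in pre_spikes) {
      fast <- fast - spec$gA_amp * biexp_kernel(time - s - 1, spec$tau_rise_A,
                                                spec$tau_decay_A)
    }
  }
  slow <- numeric(length(time))
  if (spec$receptor %in% c("GABA_B", "GABA_AB")) {
    gate <- gabab_gate(time, pre_spikes, spec)
    kern <- biexp_kernel(time, spec$tau_rise_B, spec$tau_decay_B)
    # discrete convolution of the delayed gate with the slow kernel,
    # normalized so an always-open gate would reach gB_amp
    delay_n <- round(spec$gB_onset_delay / dt)
    gate_d <- c(numeric(delay_n), gate)[seq_along(gate)]
    conv <- stats::convolve(gate_d, rev(kern), type = "open")[seq_along(gate)]
    slow <- -spec$gB_amp * conv / sum(kern)
  }
  resp <- fast + slow
  sweeps <- with_seed(spec$seed, lapply(seq_len(spec$n_repetitions), function(k) {
    scale_k <- (1 - spec$rundown_rate)^(k - 1)
    v <- spec$holding_potential + scale_k * resp +
      stats::rnorm(length(time), 0, spec$noise_sd)
    voltage_trace(time, v, cell_id = paste0("post_", spec$receptor),
                  sweep_id = paste0("rep", k),
                  sampling_rate_khz = spec$sampling_rate)
  }))
  freq <- if (length(pre_spikes) > 1) {
    1000 / stats::median(diff(pre_spikes))
  } else NA_real_
  structure(
    list(pre_spike_times = pre_spikes, post_sweeps = sweeps,
         holding_potential = spec$holding_potential, stim_frequency = freq,
         inter_stimulus_interval_s = spec$inter_stimulus_interval_s,
         patch_mode = spec$patch_mode,
         ground_truth = spec),
    class = "paired_recording"
  )
}

#' @export
print.paired_recording <- function(x, ...) {
  cat(sprintf(
    "<paired_recording> %d pre spikes (%.3g Hz), %d sweeps, %s patch\n",
    length(x$pre_spike_times), x$stim_frequency, length(x$post_sweeps),
    x$patch_mode))
  invisible(x)
}

#' Generate a synthetic gap-junction recording
#'
#' Simulates a hyperpolarizing step injected into the presynaptic cell of an
#' electrically coupled pair: the injected cell charges as an RC membrane and
#' the coupled cell follows with the given coupling coefficient.
#'
#' @param cc true coupling coefficient (post/pre steady-state deflection).
#' @param step_pa step current, pA (negative for hyperpolarizing).
#' @param r_in_mohm input resistance of the injected cell, MOhm.
#' @param tau_ms membrane time constant, ms.
#' @param noise_sd additive noise SD, mV.
#' @param n_sweeps number of repetitions.
#' @param sweep_ms sweep duration, ms.
#' @param seed integer seed.
#' @return List of class `gj_recording` with `pre_sweeps`, `post_sweeps`
#'   (lists of [voltage_trace()]), `step_window` (ms) and `ground_truth`.
#' @export
generate_gj_recording <- function(cc, step_pa = -80, r_in_mohm = 300,
                                  tau_ms = 18, noise_sd = 0.05, n_sweeps = 10,
                                  sweep_ms = 600, seed = 1) {
  dt <- 0.2
  time <- seq(0, sweep_ms - dt, by = dt)
  on <- 100; off <- 500
  defl <- step_pa * r_in_mohm / 1000
  shape <- (1 - exp(-(time - on) / tau_ms)) * (time >= on & time < off) +
    (1 - exp(-(off - on) / tau_ms)) * exp(-(time - off) / tau_ms) *
      (time >= off)
  stim <- ifelse(time >= on & time < off, step_pa, 0)
  out <- with_seed(seed, {
    mk <- function(base_defl, which, k, with_stim) {
      v <- -65 + base_defl * shape + stats::rnorm(length(time), 0, noise_sd)
      voltage_trace(time, v, if (with_stim) stim else NULL,
                    cell_id = which, sweep_id = paste0("rep", k),
                    sampling_rate_khz = 1 / dt)
    }
    list(
      pre_sweeps = lapply(seq_len(n_sweeps), function(k)
        mk(defl, "pre", k, TRUE)),
      post_sweeps = lapply(seq_len(n_sweeps), function(k)
        mk(defl * cc, "post", k, FALSE))
    )
  })
  structure(
    c(out, list(step_window = c(on, off),
                ground_truth = list(cc = cc, step_pa = step_pa,
                                    r_in_mohm = r_in_mohm))),
    class = "gj_recording"
  )
}

#' Generate a probed pair population with known connectivity
#'
#' Each unordered pair of simultaneously recorded cells is tested in both
#' directions for a synaptic connection (independent Bernoulli per ordered
#' direction with probability `p_syn_directed`) and once for a gap junction
#' (Bernoulli with probability `p_gj`).
#'
#' @param n_pairs number of probed unordered pairs.
#' @param p_syn_directed directed synaptic connection probability.
#' @param p_gj gap-junction probability per unordered pair.
#' @param seed integer seed.
#' @return A data.frame of probe records: `pair_id`, `direction`
#'   (`"1->2"`, `"2->1"` or `"gj"`), `tested`, `connected`.
#' @export
generate_pair_population <- function(n_pairs, p_syn_directed, p_gj, seed = 1) {
  if (p_syn_directed < 0 || p_syn_directed > 1 || p_gj < 0 || p_gj > 1) {
    stop("probabilities must be in [0, 1]")
  }
  with_seed(seed, {
    syn12 <- stats::runif(n_pairs) < p_syn_directed
    syn21 <- stats::runif(n_pairs) < p_syn_directed
    gj <- stats::runif(n_pairs) < p_gj
    data.frame(
      pair_id = rep(seq_len(n_pairs), 3),
      direction = rep(c("1->2", "2->1", "gj"), each = n_pairs),
      tested = TRUE,
      connected = c(syn12, syn21, gj),
      stringsAsFactors = FALSE
    )
  })
}
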