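test_that("sweep averaging is exact on constructed cases", {
  t <- seq(0, 99.9, 0.1)
  s1 <- voltage_trace(t, rep(-57, 1000))
  expect_equal(average_sweeps(list(s1, s1))$voltage, s1$voltage)
  up <- voltage_trace(t, -57 + ifelse(t > 50, 1, 0))
  dn <- voltage_trace(t, -57 - ifelse(t > 50, 1, 0))
  m <- average_sweeps(list(up, dn))
  expect_equal(m$voltage, rep(-57, 1000))
  short <- voltage_trace(seq(0, 49.9, 0.1), rep(-57, 500))
  expect_error(average_sweeps(list(s1, short)), "mismatched")
})

test_that("averaging N noisy replicates shrinks residual noise like 1/sqrt(N)", {
  set.seed(1)
  t <- seq(0, 199.9, 0.1)
  n <- 16
  sweeps <- lapply(1:n, function(k)
    voltage_trace(t, -57 + rnorm(length(t), 0, 0.5)))
  m <- average_sweeps(sweeps, baseline_ms = 50)
  expect_equal(sd(m$voltage), 0.5 / sqrt(n), tolerance = 0.15)
})

test_that("IPSP 20-80% rise time matches the closed-form biexponential", {
  tau_r <- 5; tau_d <- 40; amp <- 3
  dt <- 0.1
  t <- seq(0, 599.9, dt)
  tp <- log(tau_d / tau_r) * tau_d * tau_r / (tau_d - tau_r)
  norm <- exp(-tp / tau_d) - exp(-tp / tau_r)
  kern <- function(x) ifelse(x < 0, 0, (exp(-x / tau_d) - exp(-x / tau_r)) / norm)
  v <- -57 - amp * kern(t - 101)
  tr <- voltage_trace(t, v)
  f <- extract_ipsp(tr, pre_spike_times = 100)
  expect_true(f$detected)
  expect_equal(f$amplitude, amp, tolerance = 1e-3)
  cross <- function(frac, lo, hi) {
    stats::uniroot(function(x) kern(x) - frac, c(lo, hi))$root
  }
  rise_cf <- cross(0.8, 1e-6, tp) - cross(0.2, 1e-6, tp)
  expect_lt(abs(f$rise_time_2080 - rise_cf), dt)
  decay_cf <- cross(0.2, tp, 500) - cross(0.8, tp, 500)
  expect_lt(abs(f$decay_time_2080 - decay_cf), dt)
  # latency: onset at 5% of amplitude measured from the spike, including the
  # 1 ms kernel delay built into this trace
  lat_cf <- 1 + cross(0.05, 1e-6, tp)
  expect_lt(abs(f$latency - lat_cf), dt)
})

test_that("IPSP amplitude is baseline-offset invariant and latency shift invariant", {
  sp <- synapse_gen_spec("GABA_A", noise_sd = 0, rundown_rate = 0, seed = 1)
  rec <- generate_paired_recording(sp, 100)
  f0 <- extract_ipsp(rec)
  m <- average_sweeps(rec)
  m$voltage <- m$voltage + 11
  f1 <- extract_ipsp(m, pre_spike_times = 100)
  expect_equal(f1$amplitude, f0$amplitude, tolerance = 1e-9)

  rec2 <- generate_paired_recording(sp, 300, sweep_ms = 1800)
  f2 <- extract_ipsp(rec2)
  expect_equal(f2$latency, f0$latency, tolerance = 0.2)
})

test_that("per-sweep amplitude statistics give the CV", {
  # constant per-sweep amplitudes -> CV 0
  sp <- synapse_gen_spec("GABA_A", noise_sd = 0, rundown_rate = 0,
                         n_repetitions = 3)
  f <- extract_ipsp(generate_paired_recording(sp, 100))
  expect_equal(f$cv, 0, tolerance = 1e-9)
  # flat trace: below detection, no fabricated kinetics
  t <- seq(0, 299.9, 0.1)
  flat <- voltage_trace(t, rep(-57, length(t)))
  f0 <- extract_ipsp(flat, pre_spike_times = 100)
  expect_false(f0$detected)
  expect_null(f0$rise_time_2080)
})

test_that("the CV estimator approaches sigma/mu with many repetitions", {
  set.seed(2)
  mu <- 3; sigma <- 0.6
  t <- seq(0, 399.9, 0.1)
  kern <- ifelse(t < 101, 0, (exp(-(t - 101) / 40) - exp(-(t - 101) / 5)))
  kern <- kern / max(kern)
  cvs <- replicate(30, {
    amps <- rnorm(40, mu, sigma)
    sweeps <- lapply(amps, function(a) voltage_trace(t, -57 - a * kern))
    extract_ipsp(average_sweeps(sweeps, baseline_ms = 95),
                 pre_spike_times = 100, per_sweep_traces = sweeps)$cv
  })
  expect_equal(mean(cvs), sigma / mu, tolerance = 0.1)
})

test_that("receptor classification follows the decision rules", {
  sp_a <- synapse_gen_spec("GABA_A", noise_sd = 0.02, rundown_rate = 0, seed = 2)
  f1 <- extract_ipsp(generate_paired_recording(sp_a, 100))
  ft <- extract_ipsp(generate_paired_recording(sp_a, train_40hz()))
  expect_lt(f1$rise_time_2080, 60)
  expect_equal(classify_receptor(f1, ft)$label, "GABA_A")

  sp_b <- synapse_gen_spec("GABA_B", noise_sd = 0.02, rundown_rate = 0, seed = 2)
  f1b <- extract_ipsp(generate_paired_recording(sp_b, 100))
  ftb <- extract_ipsp(generate_paired_recording(sp_b, train_40hz()))
  lab <- classify_receptor(f1b, ftb)
  expect_equal(lab$label, "GABA_B")
  expect_false(lab$evidence$single_ap_response)
  expect_gte(lab$evidence$rise_time, 60)

  sp_ab <- synapse_gen_spec("GABA_AB", noise_sd = 0.02, rundown_rate = 0, seed = 2)
  f1ab <- extract_ipsp(generate_paired_recording(sp_ab, 100))
  ftab <- extract_ipsp(generate_paired_recording(sp_ab, train_40hz()))
  expect_equal(classify_receptor(f1ab, ftab)$label, "GABA_AB")

  expect_error(classify_receptor(NULL, NULL), "at least one")
  # totality: a below-detection pair is unclassified with a reason
  un <- classify_receptor(f0 <- structure(list(detected = FALSE),
                                          class = "ipsp_features"), NULL)
  expect_equal(un$label, "unclassified")
  expect_false(is.na(un$evidence$reason))
})

test_that("the receptor round trip holds at low noise for all three classes", {
  for (seed in 1:5) {
    for (rc in c("GABA_A", "GABA_B", "GABA_AB")) {
      sp <- synapse_gen_spec(rc, noise_sd = 0.1, rundown_rate = 0, seed = seed)
      f1 <- extract_ipsp(generate_paired_recording(sp, 100))
      ft <- extract_ipsp(generate_paired_recording(sp, train_40hz()))
      expect_equal(classify_receptor(f1, ft)$label, rc,
                   label = paste("receptor", rc, "seed", seed))
    }
  }
})

test_that("the rise-time mixture recovers two populations and is monotone", {
  set.seed(3)
  x <- c(rnorm(100, 20, 3), rnorm(100, 160, 30))
  fit <- fit_rise_time_mixture(x)
  expect_lt(abs(fit$means[1] - 20) / 20, 0.10)
  expect_lt(abs(fit$means[2] - 160) / 160, 0.10)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_gt(fit$lrt_stat, 0)

  # identical values: degenerate flagged
  expect_true(fit_rise_time_mixture(rep(5, 20))$degenerate)

  # single population: small likelihood-ratio improvement
  y <- rnorm(200, 50, 5)
  fit1 <- fit_rise_time_mixture(y)
  expect_lt(fit1$lrt_stat, 30)
  expect_gt(fit$lrt_stat, fit1$lrt_stat)
})

test_that("the mixture EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(4)
  x <- c(rnorm(150, 25, 4), rnorm(100, 140, 25))
  fit <- fit_rise_time_mixture(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
})

test_that("rundown fits recover geometric decay", {
  r <- measure_rundown(c(4, 2, 1))
  expect_equal(r$ratio, 0.5, tolerance = 1e-9)
  r1 <- measure_rundown(c(3, 3, 3, 3))
  expect_equal(r1$ratio, 1.0, tolerance = 1e-9)
  expect_error(measure_rundown(c(1, 2)), "3 repetitions")

  # generator rundown recovered within a CI across seeds
  est <- vapply(1:12, function(s) {
    sp <- synapse_gen_spec("GABA_A", rundown_rate = 0.1, noise_sd = 0.05,
                           n_repetitions = 10, seed = s)
    measure_rundown(extract_ipsp(
      generate_paired_recording(sp, 100))$per_sweep_amplitudes)$rate
  }, numeric(1))
  ci <- t.test(est, mu = 0.1)$conf.int
  expect_gte(0.1, ci[1] - 0.02)
  expect_lte(0.1, ci[2] + 0.02)

  # per-ISI comparison
  r2 <- measure_rundown(c(4, 2, 1, 5, 5, 5),
                        isi_s = c(30, 30, 30, 120, 120, 120))
  expect_equal(nrow(r2$by_isi), 2L)
  expect_equal(r2$by_isi$ratio[r2$by_isi$isi_s == 30], 0.5, tolerance = 1e-9)
  expect_equal(r2$by_isi$ratio[r2$by_isi$isi_s == 120], 1.0, tolerance = 1e-9)
})

test_that("coupling coefficients and symmetry analysis behave as constructed", {
  expect_equal(coupling_coefficient(-10, -0.5), 0.05)
  expect_error(coupling_coefficient(0, 1), "deflection")

  g12 <- generate_gj_recording(0.054, noise_sd = 0, seed = 1)
  g21 <- generate_gj_recording(0.054, noise_sd = 0, seed = 2)
  gm <- gj_analyze(g12, g21)
  expect_equal(gm$cc_12, 0.054, tolerance = 1e-6)
  expect_equal(gm$cc_12, gm$cc_21, tolerance = 1e-6)

  # noisy symmetric pair: symmetric flag at alpha 0.05 most of the time
  g12n <- generate_gj_recording(0.054, noise_sd = 0.05, n_sweeps = 15, seed = 3)
  g21n <- generate_gj_recording(0.054, noise_sd = 0.05, n_sweeps = 15, seed = 4)
  gmn <- gj_analyze(g12n, g21n)
  expect_equal(gmn$cc_12, 0.054, tolerance = 0.25)
  # strongly asymmetric pair is flagged
  g21a <- generate_gj_recording(0.2, noise_sd = 0.02, n_sweeps = 15, seed = 5)
  expect_false(gj_analyze(g12n, g21a)$symmetric)
})

test_that("pharmacology epochs decompose into fast and slow components", {
  acc <- pharmacology_account(list(baseline = 4.83, gabazine = 1.66,
                                   gabazine_plus_cgp = 0.64, washout = 3.27))
  expect_equal(acc$fast_component, 4.83 - 1.66)
  expect_equal(acc$slow_component, 1.66 - 0.64)
  expect_equal(acc$residual, 0.64)
  expect_equal(acc$recovery_fraction, 3.27 / 4.83)

  eq <- pharmacology_account(list(baseline = 2, gabazine = 2,
                                  gabazine_plus_cgp = 2, washout = 2))
  expect_equal(eq$fast_component, 0)
  expect_equal(eq$slow_component, 0)

  part <- pharmacology_account(list(baseline = 3, gabazine = 1))
  expect_true("washout" %in% part$missing)
  expect_true(is.na(part$recovery_fraction))
})

test_that("generated mixed connections decompose like the block experiment", {
  # block the fast component in the generator and compare epochs
  ab <- synapse_gen_spec("GABA_AB", noise_sd = 0, rundown_rate = 0, seed = 6)
  b_only <- synapse_gen_spec("GABA_B", noise_sd = 0, rundown_rate = 0, seed = 6)
  amp_base <- extract_ipsp(generate_paired_recording(ab, train_40hz()))$amplitude
  amp_gbz <- extract_ipsp(generate_paired_recording(b_only, train_40hz()))$amplitude
  acc <- pharmacology_account(list(baseline = amp_base, gabazine = amp_gbz,
                                   gabazine_plus_cgp = 0, washout = amp_base))
  expect_gt(acc$fast_component, 0)
  expect_gt(acc$slow_component, 0)
  expect_equal(acc$fast_component + acc$slow_component, amp_base,
               tolerance = 1e-9)
})
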