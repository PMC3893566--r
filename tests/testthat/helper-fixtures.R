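# Small programmatic fixtures shared across tests.

# Hand-built morphology: soma + one axon trunk + one dendrite Y.
# All segments axis-aligned with known lengths, for hand-checkable features.
toy_morphology <- function() {
  nodes <- data.frame(
    id        = 1:10,
    parent    = c(-1, 1, 2, 3, 1, 5, 6, 6, 1, 9),
    structure = c(1, 2, 2, 2, 3, 3, 3, 3, 3, 3),
    x = c(0, 10, 20, 30, 0, 0, 10, -10, 0, 0),
    y = c(0, 0, 5, 0, 10, 20, 30, 30, -10, -20),
    z = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    radius = c(7, 0.3, 0.3, 0.3, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  )
  morphology(nodes, cell_id = "toy")
}

# random small tree for oracle comparisons: grows n_nodes nodes by attaching
# each to a random existing node of its arbor
random_small_morphology <- function(seed, n_axon = 30, n_dend = 20) {
  set.seed(seed)
  nodes <- list(c(1, -1, 1, 0, 0, 0, 6))
  id <- 1L
  add_arbor <- function(code, n, nodes, id) {
    arbor_ids <- integer(0)
    for (i in seq_len(n)) {
      parent <- if (length(arbor_ids) == 0) 1L else
        arbor_ids[sample.int(length(arbor_ids), 1)]
      prev <- nodes[[parent]]
      pos <- prev[4:6] + stats::rnorm(3, sd = 6)
      id <- id + 1L
      nodes[[id]] <- c(id, prev[1], code, pos, stats::runif(1, 0.2, 1))
      arbor_ids <- c(arbor_ids, id)
    }
    list(nodes = nodes, id = id)
  }
  r <- add_arbor(2, n_axon, nodes, id)
  r <- add_arbor(3, n_dend, r$nodes, r$id)
  m <- do.call(rbind, r$nodes)
  morphology(data.frame(id = m[, 1], parent = m[, 2], structure = m[, 3],
                        x = m[, 4], y = m[, 5], z = m[, 6], radius = m[, 7]),
             cell_id = paste0("rand", seed))
}

# apply a rigid transform (rotation about z by deg + translation) to a morphology
transform_morphology <- function(morph, rot_deg = 0, shift = c(0, 0, 0),
                                 scale = 1) {
  th <- rot_deg * pi / 180
  x <- morph$nodes$x * scale; y <- morph$nodes$y * scale
  z <- morph$nodes$z * scale
  morph$nodes$x <- cos(th) * x - sin(th) * y + shift[1]
  morph$nodes$y <- sin(th) * x + cos(th) * y + shift[2]
  morph$nodes$z <- z + shift[3]
  morph$nodes$radius <- morph$nodes$radius * scale
  morph
}

# analytic RC step-response trace (hyperpolarizing step)
rc_step_trace <- function(step_pa = -100, r_in = 300, tau = 18,
                          sweep_ms = 1000, on = 100, off = 700, dt = 0.1,
                          baseline = -65) {
  time <- seq(0, sweep_ms - dt, by = dt)
  defl <- step_pa * r_in / 1000
  v <- baseline +
    defl * (1 - exp(-(time - on) / tau)) * (time >= on & time < off) +
    defl * (1 - exp(-(off - on) / tau)) * exp(-(time - off) / tau) *
      (time >= off)
  stim <- ifelse(time >= on & time < off, step_pa, 0)
  voltage_trace(time, v, stim, cell_id = "rc", sweep_id = "step")
}

# delta-pulse trace with single-exponential decay of known tau
delta_pulse_trace <- function(tau = 18, amp = -8, sweep_ms = 400,
                              pulse_on = 50, pulse_ms = 1, dt = 0.1,
                              baseline = -65) {
  time <- seq(0, sweep_ms - dt, by = dt)
  t_end <- pulse_on + pulse_ms
  v <- baseline + ifelse(time >= t_end, amp * exp(-(time - t_end) / tau),
                         ifelse(time >= pulse_on, amp, 0))
  stim <- ifelse(time >= pulse_on & time < t_end, -500, 0)
  voltage_trace(time, v, stim, cell_id = "rc", sweep_id = "delta")
}

# 40 Hz presynaptic train starting at 100 ms
train_40hz <- function(n = 15) 100 + seq(0, by = 25, length.out = n)
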