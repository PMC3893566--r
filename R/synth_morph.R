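#' Specification for a synthetic neuron morphology
#'
#' Parameters of the stochastic branching-tree generator for one of the six
#' layer-1 morphological classes. Arbors grow as chains of segments with a
#' prescribed mean path length and tortuosity, confined to a bounding box that
#' sets the target horizontal/vertical extents; bifurcation is Bernoulli per
#' segment end up to a maximum centrifugal order.
#'
#' @param mtype one of `"NGC-DA"`, `"NGC-SA"`, `"HAC"`, `"DAC"`, `"LAC"`,
#'   `"SAC"`.
#' @param axon_h_extent,axon_v_extent target axonal extents, um.
#' @param dend_h_extent,dend_v_extent target dendritic extents, um.
#' @param axon_segment_length,dend_segment_length mean segment path length, um.
#' @param axon_tortuosity,dend_tortuosity target segment tortuosity (>= 1).
#' @param axon_branch_prob,dend_branch_prob bifurcation probability per
#'   segment end (< 1).
#' @param axon_max_order,dend_max_order maximum centrifugal branch order.
#' @param n_dendrites number of dendritic trunks.
#' @param n_axon_trunks number of axonal trunks.
#' @param soma_radius um.
#' @param z_extent slice-depth spread of the arbor, um.
#' @param descending_collateral add a collateral descending below the soma
#'   toward the lower layers (DAC hallmark).
#' @param max_segments hard cap on segments per arbor (keeps the
#'   supercritical branching process bounded).
#' @param seed integer seed.
#' @return An object of class `morph_gen_spec`.
#' @export
morph_gen_spec <- function(mtype,
                           axon_h_extent, axon_v_extent,
                           dend_h_extent, dend_v_extent,
                           axon_segment_length = 45, dend_segment_length = 35,
                           axon_tortuosity = 1.27, dend_tortuosity = 1.25,
                           axon_branch_prob = 0.55, dend_branch_prob = 0.5,
                           axon_max_order = 16, dend_max_order = 7,
                           n_dendrites = 5, n_axon_trunks = 2,
                           soma_radius = 7.4, z_extent = 80,
                           descending_collateral = FALSE,
                           max_segments = 700, seed = 1) {
  mtype <- match.arg(mtype, c("NGC-DA", "NGC-SA", "HAC", "DAC", "LAC", "SAC"))
  lens <- c(axon_h_extent, axon_v_extent, dend_h_extent, dend_v_extent,
            axon_segment_length, dend_segment_length, soma_radius, z_extent)
  if (any(lens <= 0)) stop("all lengths must be > 0")
  if (axon_tortuosity < 1 || dend_tortuosity < 1) {
    stop("tortuosity targets must be >= 1")
  }
  if (axon_branch_prob >= 1 || dend_branch_prob >= 1) {
    stop("branch_prob of 1 with no depth bound gives an unbounded tree")
  }
  structure(
    list(mtype = mtype,
         axon_h_extent = axon_h_extent, axon_v_extent = axon_v_extent,
         dend_h_extent = dend_h_extent, dend_v_extent = dend_v_extent,
         axon_segment_length = axon_segment_length,
         dend_segment_length = dend_segment_length,
         axon_tortuosity = axon_tortuosity, dend_tortuosity = dend_tortuosity,
         axon_branch_prob = axon_branch_prob,
         dend_branch_prob = dend_branch_prob,
         axon_max_order = as.integer(axon_max_order),
         dend_max_order = as.integer(dend_max_order),
         n_dendrites = as.integer(n_dendrites),
         n_axon_trunks = as.integer(n_axon_trunks),
         soma_radius = soma_radius, z_extent = z_extent,
         descending_collateral = isTRUE(descending_collateral),
         max_segments = as.integer(max_segments), seed = as.integer(seed)),
    class = "morph_gen_spec"
  )
}

#' Per-class generator defaults for the six morphological types
#'
#' Class targets (extents, segment lengths, tortuosity, dendrite counts,
#' maximum orders) follow the reported per-class morphometric means: e.g. the
#' horizontal axon cell (HAC) axon spans ~826 x 202 um (H/V ~ 4.5), the
#' descending-collateral cell (DAC) axon reaches ~602 um vertically with a
#' collateral toward the lower layers, neurogliaform dense-arbor (NGC-DA)
#' dendritic segments average ~26 um, and the small axon cell (SAC) axon has
#' tortuosity ~1.22.
#'
#' @param mtype morphological class label.
#' @param seed integer seed.
#' @return A `morph_gen_spec`.
#' @export
mtype_gen_defaults <- function(mtype, seed = 1) {
  switch(match.arg(mtype, c("NGC-DA", "NGC-SA", "HAC", "DAC", "LAC", "SAC")),
    "NGC-DA" = morph_gen_spec("NGC-DA", 481, 263, 122, 133,
                              axon_segment_length = 42,
                              dend_segment_length = 26,
                              axon_tortuosity = 1.30, dend_tortuosity = 1.28,
                              axon_branch_prob = 0.56, axon_max_order = 16,
                              dend_max_order = 7, n_dendrites = 5,
                              seed = seed),
    "NGC-SA" = morph_gen_spec("NGC-SA", 513, 163, 191, 150,
                              axon_segment_length = 45,
                              dend_segment_length = 33,
                              axon_tortuosity = 1.29, dend_tortuosity = 1.24,
                              axon_branch_prob = 0.54, axon_max_order = 15,
                              dend_max_order = 7, n_dendrites = 6,
                              seed = seed),
    "HAC" = morph_gen_spec("HAC", 826, 202, 227, 170,
                           axon_segment_length = 67, dend_segment_length = 45,
                           axon_tortuosity = 1.27, dend_tortuosity = 1.29,
                           axon_branch_prob = 0.54, axon_max_order = 14,
                           dend_max_order = 6, n_dendrites = 5, seed = seed),
    "DAC" = morph_gen_spec("DAC", 1035, 602, 305, 209,
                           axon_segment_length = 60, dend_segment_length = 50,
                           axon_tortuosity = 1.24, dend_tortuosity = 1.25,
                           axon_branch_prob = 0.55, axon_max_order = 20,
                           dend_max_order = 7, n_dendrites = 6,
                           descending_collateral = TRUE, seed = seed),
    "LAC" = morph_gen_spec("LAC", 879, 316, 211, 187,
                           axon_segment_length = 44, dend_segment_length = 34,
                           axon_tortuosity = 1.31, dend_tortuosity = 1.26,
                           axon_branch_prob = 0.56, axon_max_order = 21,
                           dend_max_order = 7, n_dendrites = 6, seed = seed),
    "SAC" = morph_gen_spec("SAC", 411, 251, 218, 194,
                           axon_segment_length = 45, dend_segment_length = 38,
                           axon_tortuosity = 1.22, dend_tortuosity = 1.18,
                           axon_branch_prob = 0.50, axon_max_order = 12,
                           dend_max_order = 6, n_dendrites = 5, seed = seed)
  )
}

# unit vector, horizontally biased (z compressed for the slice geometry)
random_direction <- function(hbias = 1) {
  v <- c(stats::rnorm(1), stats::rnorm(1) / hbias, stats::rnorm(1) * 0.4)
  v / sqrt(sum(v^2))
}

# rotate `v` by `angle_deg` about a random axis perpendicular to it
tilt_direction <- function(v, angle_deg) {
  a <- stats::rnorm(3)
  a <- a - sum(a * v) * v
  na <- sqrt(sum(a^2))
  if (na < 1e-12) return(v)
  a <- a / na
  th <- angle_deg * pi / 180
  w <- cos(th) * v + sin(th) * a
  w / sqrt(sum(w^2))
}

# Wiggle amplitude (as a fraction of the chord) making the discrete sinusoid
# polyline of n points have path length = tortuosity * chord. Depends only on
# (n, tortuosity); callers cache the result per point count.
segment_wiggle_ratio <- function(n, tortuosity) {
  if (tortuosity <= 1 + 1e-9) return(0)
  tfrac <- seq(0, 1, length.out = n)
  wig <- sin(2 * pi * tfrac * 2)  # two wiggle periods per segment
  plen <- function(a) {
    dx <- diff(tfrac)
    dw <- diff(wig) * a
    sum(sqrt(dx^2 + dw^2))
  }
  upper <- 1
  while (plen(upper) < tortuosity) upper <- upper * 2
  stats::uniroot(function(a) plen(a) - tortuosity, c(0, upper))$root
}

# Build the point chain of one segment: a straight chord plus a perpendicular
# sinusoidal displacement calibrated so the polyline path length equals
# tortuosity * chord.
segment_points <- function(start, direction, chord, n, amp_ratio) {
  tfrac <- seq(0, 1, length.out = n)
  base <- outer(tfrac * chord, direction) + matrix(start, n, 3, byrow = TRUE)
  if (amp_ratio == 0) return(base)
  perp <- stats::rnorm(3)
  perp <- perp - sum(perp * direction) * direction
  perp <- perp / sqrt(sum(perp^2))
  base + outer(sin(2 * pi * tfrac * 2) * amp_ratio * chord, perp)
}

# Bounce the growth direction off the box walls so the segment chord endpoint
# stays inside; if the start is already outside, steer toward the box center.
bounce_direction <- function(pos, dir, chord, box) {
  for (ax in 1:3) {
    e <- pos[ax] + chord * dir[ax]
    if (e < box[1, ax] || e > box[2, ax]) dir[ax] <- -dir[ax]
    e <- pos[ax] + chord * dir[ax]
    if (e < box[1, ax] || e > box[2, ax]) {
      ctr <- (box[1, ] + box[2, ]) / 2
      d <- ctr - pos
      nd <- sqrt(sum(d^2))
      if (nd > 0) return(d / nd)
    }
  }
  dir
}

# grow one arbor type; returns node data.frame rows appended to env$nodes.
# Segments of order <= force_order always bifurcate (when branch_prob > 0) so
# the branching process does not go extinct at the trunk.
grow_arbor <- function(env, structure_code, n_trunks, box, seg_len_mean,
                       tortuosity, branch_prob, max_order, radius,
                       trunk_radius, soma_id, max_segments, hbias = 1.5,
                       force_order = 3L, h_drift = 0) {
  n_seg <- 0L
  wiggle_cache <- new.env()
  amp_ratio_for <- function(n) {
    key <- as.character(n)
    if (is.null(wiggle_cache[[key]])) {
      wiggle_cache[[key]] <- segment_wiggle_ratio(n, tortuosity)
    }
    wiggle_cache[[key]]
  }
  for (tr in seq_len(n_trunks)) {
    dir0 <- if (structure_code == 2L) {
      # axon trunks leave the soma in alternating horizontal directions
      d <- c(if (tr %% 2 == 1) 1 else -1, stats::rnorm(1, 0, 0.3),
             stats::rnorm(1, 0, 0.15))
      d / sqrt(sum(d^2))
    } else random_direction(hbias)
    # queue entries: position, direction, order, parent node id
    queue <- list(list(pos = c(0, 0, 0) + dir0 * env$soma_radius,
                       dir = dir0, order = 1L, parent = soma_id,
                       first = TRUE))
    while (length(queue) > 0 && n_seg < max_segments) {
      tip <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      plen <- stats::rgamma(1, shape = 6, rate = 6 / seg_len_mean)
      plen <- max(plen, 8)
      chord <- plen / tortuosity
      n_pts <- max(3L, ceiling(plen / 5) + 1L)
      dir <- tip$dir
      if (h_drift > 0) {
        # horizontal elongation: tips keep drifting outward along x
        dir <- dir + c(h_drift * sign(dir[1] + 1e-12), 0, 0)
        dir <- dir / sqrt(sum(dir^2))
      }
      dir <- bounce_direction(tip$pos, dir, chord, box)
      pts <- segment_points(tip$pos, dir, chord, n_pts, amp_ratio_for(n_pts))
      parent <- tip$parent
      rad <- if (tip$first && tip$order == 1L) trunk_radius else radius
      for (i in seq_len(nrow(pts))[-1]) {
        env$id <- env$id + 1L
        env$nodes[[length(env$nodes) + 1L]] <-
          c(env$id, parent, structure_code, pts[i, ], rad)
        parent <- env$id
        rad <- radius
      }
      n_seg <- n_seg + 1L
      end_dir <- pts[nrow(pts), ] - pts[nrow(pts) - 1, ]
      nd <- sqrt(sum(end_dir^2))
      end_dir <- if (nd > 0) end_dir / nd else tip$dir
      p_eff <- if (branch_prob > 0 && tip$order <= force_order) 1 else branch_prob
      if (tip$order < max_order && stats::runif(1) < p_eff) {
        ang <- stats::rnorm(2, mean = 28, sd = 6)
        for (k in 1:2) {
          queue[[length(queue) + 1L]] <- list(
            pos = pts[nrow(pts), ], dir = tilt_direction(end_dir, ang[k]),
            order = tip$order + 1L, parent = parent, first = FALSE)
        }
      }
    }
  }
  invisible(NULL)
}

#' Generate a synthetic neuron morphology
#'
#' Grows dendritic and axonal arbors as stochastic branching trees of
#' tortuosity-calibrated segments inside class-specific bounding boxes, so
#' that arbor extents approach the class targets. DAC specs additionally grow
#' a straight descending axon collateral crossing at least 100 um below the
#' soma. Deterministic for a fixed spec.
#'
#' @param spec a [morph_gen_spec()].
#' @return A [morphology()] with attribute `ground_truth` (the spec).
#' @export
generate_morphology <- function(spec) {
  stopifnot(inherits(spec, "morph_gen_spec"))
  env <- new.env()
  env$id <- 1L
  env$soma_radius <- spec$soma_radius
  env$nodes <- list(c(1, -1, 1, 0, 0, 0, spec$soma_radius))
  with_seed(spec$seed, {
    hd <- spec$dend_h_extent / 2; vd <- spec$dend_v_extent / 2
    dend_box <- rbind(c(-hd, -vd, -spec$z_extent / 2),
                      c(hd, vd, spec$z_extent / 2))
    grow_arbor(env, 3L, spec$n_dendrites, dend_box,
               spec$dend_segment_length, spec$dend_tortuosity,
               spec$dend_branch_prob, spec$dend_max_order,
               radius = 0.5, trunk_radius = 1.0, soma_id = 1L,
               max_segments = min(spec$max_segments, 200L), hbias = 1)
    ha <- spec$axon_h_extent / 2
    if (spec$descending_collateral) {
      # descending-axon class: the box extends mostly below the soma
      axon_box <- rbind(c(-ha, -0.85 * spec$axon_v_extent,
                          -spec$z_extent / 2),
                        c(ha, 0.15 * spec$axon_v_extent, spec$z_extent / 2))
    } else {
      va <- spec$axon_v_extent / 2
      axon_box <- rbind(c(-ha, -va, -spec$z_extent / 2),
                        c(ha, va, spec$z_extent / 2))
    }
    grow_arbor(env, 2L, spec$n_axon_trunks, axon_box,
               spec$axon_segment_length, spec$axon_tortuosity,
               spec$axon_branch_prob, spec$axon_max_order,
               radius = 0.3, trunk_radius = 0.5, soma_id = 1L,
               max_segments = spec$max_segments, hbias = 2,
               h_drift = 0.3)
    if (spec$descending_collateral) {
      # straight collateral from near the soma down past -100 um
      depth <- max(150, 0.7 * spec$axon_v_extent)
      start <- c(0, 0, 0) + c(0.5, -1, 0) / sqrt(1.25) * spec$soma_radius
      npts <- ceiling(depth / 10)
      ys <- seq(start[2], -depth, length.out = npts)
      parent <- 1L
      for (i in seq_len(npts)) {
        env$id <- env$id + 1L
        env$nodes[[length(env$nodes) + 1L]] <-
          c(env$id, parent, 2, start[1] + 0.1 * i, ys[i], start[3], 0.3)
        parent <- env$id
      }
    }
  })
  m <- do.call(rbind, env$nodes)
  nodes <- data.frame(id = m[, 1], parent = m[, 2], structure = m[, 3],
                      x = m[, 4], y = m[, 5], z = m[, 6], radius = m[, 7])
  out <- morphology(nodes, cell_id = sprintf("%s_s%d", spec$mtype, spec$seed))
  attr(out, "ground_truth") <- spec
  out
}
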