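test_that("shrinkage correction rescales z only", {
  m <- toy_morphology()
  m$nodes$z <- seq_len(nrow(m$nodes))
  c1 <- shrinkage_correct(m, measured_thickness = 150)
  expect_equal(c1$nodes$z, m$nodes$z * 2)
  expect_equal(c1$nodes$x, m$nodes$x)
  expect_equal(c1$nodes$y, m$nodes$y)
  expect_equal(shrinkage_correct(m, 300)$nodes$z, m$nodes$z)
  # single point (1, 2, 3) at measured 200 um -> (1, 2, 4.5)
  p <- morphology(data.frame(id = 1, parent = -1, structure = 1,
                             x = 1, y = 2, z = 3, radius = 5))
  expect_equal(shrinkage_correct(p, 200)$nodes$z, 4.5)
  expect_error(shrinkage_correct(m, 400), "measured")
})

test_that("segment decomposition handles unbranched and Y-shaped arbors", {
  # unbranched 100 um axon
  nodes <- data.frame(id = 1:3, parent = c(-1, 1, 2), structure = c(1, 2, 2),
                      x = c(0, 50, 100), y = 0, z = 0,
                      radius = c(5, 0.5, 0.5))
  segs <- extract_segments(morphology(nodes), "axon")
  expect_length(segs, 1L)
  expect_equal(segs[[1]]$order, 1L)
  expect_equal(segs[[1]]$path_length, 50)  # soma-attachment edge excluded

  # symmetric Y: 3 segments, max order 2
  y <- data.frame(id = 1:6, parent = c(-1, 1, 2, 3, 3, 1),
                  structure = c(1, 2, 2, 2, 2, 3),
                  x = c(0, 0, 0, -10, 10, 5), y = c(0, 10, 20, 30, 30, 0),
                  z = 0, radius = c(5, rep(0.5, 5)))
  segs <- extract_segments(morphology(y), "axon")
  expect_length(segs, 3L)
  expect_equal(max(vapply(segs, `[[`, integer(1), "order")), 2L)
})

test_that("segment path lengths partition the total arbor length", {
  for (seed in c(1, 7)) {
    m <- generate_morphology(mtype_gen_defaults("LAC", seed = seed))
    for (filt in c("axon", "dendrite")) {
      segs <- extract_segments(m, filt)
      total <- compute_moments_density(m, filt)$total_length
      expect_equal(sum(vapply(segs, `[[`, numeric(1), "path_length")), total,
                   tolerance = 1e-9)
    }
  }
})

test_that("segment count equals a brute-force recount from the branch points", {
  m <- generate_morphology(mtype_gen_defaults("LAC", seed = 5))
  segs <- extract_segments(m, "axon")
  # independent count: trunks + children spawned at axonal branch points
  nd <- m$nodes
  pidx <- match(nd$parent, nd$id)
  inf <- nd$structure == 2L
  nkids <- tabulate(pidx[inf & !is.na(pidx)], nbins = nrow(nd))
  trunks <- sum(inf & (is.na(pidx) | !inf[pidx]))
  daughters <- sum(nkids[inf] [nkids[inf] >= 2])
  expect_equal(length(segs), trunks + daughters)
})

test_that("extents and H/V ratios follow the coordinate ranges", {
  nodes <- data.frame(id = 1:4, parent = c(-1, 1, 2, 3),
                      structure = c(1, 2, 2, 2),
                      x = c(0, -50, 0, 50), y = c(0, 0, 25, 12), z = 0,
                      radius = c(5, 0.5, 0.5, 0.5))
  ex <- compute_extents(morphology(nodes), "axon")
  expect_equal(ex$h_extent, 100)
  expect_equal(ex$v_extent, 25)
  expect_equal(ex$hv_ratio, 4.0)
  # single node: degenerate, flagged, ratio infinite rather than dropped
  single <- morphology(data.frame(id = 1:2, parent = c(-1, 1),
                                  structure = c(1, 2), x = 0, y = 0, z = 0,
                                  radius = c(5, 0.5)))
  ex1 <- compute_extents(single, "axon")
  expect_equal(ex1$h_extent, 0)
  expect_true(ex1$degenerate)
  expect_identical(ex1$hv_ratio, Inf)
})

test_that("tortuosity is path over chord", {
  straight <- list(pts = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                   path_length = 2, euclidean_length = 2)
  expect_equal(compute_tortuosity(straight), 1.0)
  elbow <- list(pts = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
                path_length = 2, euclidean_length = sqrt(2))
  expect_equal(compute_tortuosity(elbow), 2 / sqrt(2), tolerance = 1e-12)
  loop <- list(pts = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0)),
               path_length = 2, euclidean_length = 0)
  expect_warning(expect_true(is.na(compute_tortuosity(loop))), "coincident")
})

test_that("branch angles match direct geometry on hand-built trees", {
  # symmetric Y with 90 degrees between straight daughters
  ynodes <- data.frame(
    id = 1:8, parent = c(-1, 1, 2, 3, 4, 3, 6, 1),
    structure = c(1, 2, 2, 2, 2, 2, 2, 3),
    x = c(0, 0, 0, 10, 20, -10, -20, 3),
    y = c(0, 10, 20, 30, 40, 30, 40, 0),
    z = 0, radius = c(5, rep(0.4, 7)))
  ang <- compute_branch_angles(morphology(ynodes), "axon")
  expect_equal(ang$n_bifurcations, 1L)
  expect_equal(ang$local, 90, tolerance = 1e-9)
  expect_equal(ang$maximum, 90, tolerance = 1e-9)
  expect_equal(ang$planar, 90, tolerance = 1e-9)
  expect_equal(ang$local_spline, 90, tolerance = 1e-9)

  # colinear daughters: 0 degrees
  cn <- data.frame(
    id = 1:6, parent = c(-1, 1, 2, 3, 3, 1),
    structure = c(1, 2, 2, 2, 2, 3),
    x = c(0, 0, 0, 5, 10, 2), y = c(0, 5, 10, 15, 20, 0), z = 0,
    radius = c(5, rep(0.4, 5)))
  ang <- compute_branch_angles(morphology(cn), "axon")
  expect_lt(ang$local, 1e-5)
})

test_that("local angles match a brute-force arccos oracle on random trees", {
  for (seed in 1:20) {
    m <- random_small_morphology(seed)
    ang <- compute_branch_angles(m, "axon")
    if (ang$n_bifurcations == 0) next
    # oracle: recompute local angles directly from the node table
    nd <- m$nodes
    pidx <- match(nd$parent, nd$id)
    inf <- nd$structure == 2L
    oracle <- c()
    for (b in which(inf)) {
      kids <- which(!is.na(pidx) & pidx == b & inf)
      if (length(kids) < 2) next
      pairs <- utils::combn(kids, 2)
      best <- -Inf
      for (k in seq_len(ncol(pairs))) {
        u <- unlist(nd[pairs[1, k], c("x", "y", "z")]) -
          unlist(nd[b, c("x", "y", "z")])
        v <- unlist(nd[pairs[2, k], c("x", "y", "z")]) -
          unlist(nd[b, c("x", "y", "z")])
        a <- acos(max(-1, min(1, sum(u * v) /
                                sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
        best <- max(best, a)
      }
      oracle <- c(oracle, best)
    }
    expect_equal(ang$local, mean(oracle), tolerance = 1e-6)
  }
})

test_that("moments vanish by symmetry and match the discretization oracle", {
  # single straight segment centred on the soma
  ctr <- morphology(data.frame(
    id = 1:5, parent = c(-1, 1, 2, 3, 1), structure = c(1, 2, 2, 2, 3),
    x = c(0, -50, 0, 50, 5), y = 0, z = 0,
    radius = c(5, 0.4, 0.4, 0.4, 0.4)))
  md <- compute_moments_density(ctr, "axon")
  expect_equal(unname(md$moment1), c(0, 0, 0), tolerance = 1e-9)
  expect_gt(md$moment2[["x"]], 0)

  for (seed in 1:5) {
    m <- random_small_morphology(seed)
    md <- compute_moments_density(m, "axon")
    orc <- oracle_features(m)
    expect_equal(unname(md$moment1),
                 unname(orc[c("axon_moment1_x", "axon_moment1_y",
                              "axon_moment1_z")]), tolerance = 0.01)
    expect_equal(unname(md$moment2),
                 unname(orc[c("axon_moment2_x", "axon_moment2_y",
                              "axon_moment2_z")]), tolerance = 0.01)
  }
})

test_that("the emitted battery has 44 features with hand-checkable totals", {
  m <- toy_morphology()
  fv <- compute_feature_vector(m)
  expect_length(fv$features, 44L)
  expect_identical(names(fv$features), morphometric_feature_names())
  # toy tree (arbor edges only; the soma-attachment edge is not neurite
  # cable): two diagonal axon edges of sqrt(125); dendrite trunk 10, two
  # diagonal daughters of sqrt(200), second trunk 10
  expect_equal(fv$features[["axon_total_length"]], 2 * sqrt(125))
  expect_equal(fv$features[["basal_total_length"]], 20 + 2 * sqrt(200))
  expect_equal(fv$features[["basal_n_trunks"]], 2)
  expect_equal(fv$features[["basal_max_degree"]], 2)
})

test_that("bouton density is markers per axon length", {
  # 100 um axon, 20 markers on it -> 0.20 per um
  nodes <- data.frame(id = 1:13, parent = c(-1, 1:10, 1, 12),
                      structure = c(1, rep(2, 10), 3, 3),
                      x = c(0, seq(10, 100, by = 10), 3, 6),
                      y = c(rep(0, 12), 5),
                      z = 0,
                      radius = c(5, rep(0.4, 12)))
  m <- morphology(nodes)
  markers <- cbind(rep(seq(10, 100, by = 10), 2), 0.5, 0)
  fv <- compute_feature_vector(m, markers = markers)
  expect_equal(fv$bouton_density, 20 / 90)  # 90 um of axon edges
  far <- rbind(markers, c(50, 500, 0))
  expect_error(compute_feature_vector(m, markers = far), "marker")
})

test_that("every feature matches the independent traversal oracle", {
  for (seed in 1:20) {
    m <- random_small_morphology(seed)
    fv <- compute_feature_vector(m)$features
    orc <- oracle_features(m)
    for (f in names(orc)) {
      # mixed tolerance: relative for large values, absolute near zero
      # (moments checked against a 0.1 um discretization)
      expect_lt(abs(fv[[f]] - orc[[f]]), 0.011 * max(1, abs(orc[[f]])),
                label = paste0("tree ", seed, " feature ", f,
                               " |impl-oracle|"))
    }
  }
})

test_that("features obey scaling, translation and rotation invariances", {
  m <- random_small_morphology(3)
  f0 <- compute_feature_vector(m)$features
  a0 <- compute_branch_angles(m, "axon")

  # rigid translation: everything invariant
  ft <- compute_feature_vector(transform_morphology(m, shift = c(30, -40, 10)))$features
  expect_equal(unname(ft), unname(f0), tolerance = 1e-9)

  # uniform scaling: lengths scale linearly, tortuosity and H/V invariant,
  # angles invariant
  s <- 2.5
  ms <- transform_morphology(m, scale = s)
  fs <- compute_feature_vector(ms)$features
  as <- compute_branch_angles(ms, "axon")
  for (f in c("axon_total_length", "basal_total_length",
              "axon_max_path_length", "axon_horizontal_range")) {
    expect_equal(fs[[f]], s * f0[[f]], tolerance = 1e-9)
  }
  expect_equal(fs[["axon_tortuosity"]], f0[["axon_tortuosity"]],
               tolerance = 1e-9)
  expect_equal(fs[["axon_hv_ratio"]], f0[["axon_hv_ratio"]], tolerance = 1e-9)
  expect_equal(as$local, a0$local, tolerance = 1e-9)

  # 90 degree rotation about z: horizontal and vertical swap
  mr <- transform_morphology(m, rot_deg = 90)
  fr <- compute_feature_vector(mr)$features
  expect_equal(fr[["axon_horizontal_range"]], f0[["axon_vertical_range"]],
               tolerance = 1e-9)
  expect_equal(fr[["axon_vertical_range"]], f0[["axon_horizontal_range"]],
               tolerance = 1e-9)
  expect_equal(fr[["axon_total_length"]], f0[["axon_total_length"]],
               tolerance = 1e-9)
})

test_that("morphometry_table emits one row per cell with the 44 columns", {
  morphs <- list(generate_morphology(mtype_gen_defaults("SAC", seed = 1)),
                 generate_morphology(mtype_gen_defaults("HAC", seed = 1)))
  tab <- morphometry_table(morphs)
  expect_equal(nrow(tab), 2L)
  expect_equal(ncol(tab), 45L)  # cell_id + 44 features
  expect_identical(names(tab)[-1], morphometric_feature_names())
})
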