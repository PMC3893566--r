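#' Shrinkage correction of a reconstruction
#'
#' Histological processing shrinks the slice along its depth (z) axis;
#' reconstructions are corrected by rescaling z from the measured post-hoc
#' thickness back to the original slice thickness. In-plane (x-y) shrinkage is
#' small and not corrected.
#'
#' @param morph a [morphology()].
#' @param measured_thickness measured slice thickness after processing, um.
#' @param original_thickness original slice thickness, um (default 300).
#' @return The corrected `morphology` (z scaled by original/measured).
#' @export
shrinkage_correct <- function(morph, measured_thickness,
                              original_thickness = 300) {
  stopifnot(inherits(morph, "morphology"))
  if (measured_thickness <= 0 || measured_thickness > original_thickness) {
    stop("measured thickness must be in (0, original_thickness]")
  }
  morph$nodes$z <- morph$nodes$z * (original_thickness / measured_thickness)
  morph
}

# --- internal tree helpers ---------------------------------------------------

# resolve a neurite filter to SWC structure codes
filter_codes <- function(neurite_filter) {
  if (is.numeric(neurite_filter)) return(as.integer(neurite_filter))
  switch(match.arg(neurite_filter, c("axon", "dendrite", "soma", "all")),
         axon = 2L, dendrite = 3L, soma = 1L, all = c(1L, 2L, 3L))
}

# children index list: for each node row, integer vector of child rows
children_of <- function(nodes) {
  kids <- vector("list", nrow(nodes))
  pid <- match(nodes$parent, nodes$id)
  for (i in seq_len(nrow(nodes))) {
    p <- pid[i]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  kids
}

soma_center <- function(morph) {
  s <- morph$nodes[morph$nodes$structure == 1L, ]
  if (nrow(s) == 0) s <- morph$nodes[1, ]
  c(x = mean(s$x), y = mean(s$y), z = mean(s$z))
}

#' Decompose a neurite arbor into segments
#'
#' A segment is the chain of points between consecutive branch points, or
#' between a branch point (or the trunk origin at the soma) and a terminal
#' tip. Branch order is assigned centrifugally with the trunk segment at
#' order 1, incrementing at every bifurcation.
#'
#' @param morph a [morphology()].
#' @param neurite_filter `"axon"`, `"dendrite"`, or a vector of SWC structure
#'   codes.
#' @return A list of segments; each has `pts` (n x 3 matrix), `radii`,
#'   `path_length`, `euclidean_length`, `order`, `trunk` (trunk index it
#'   belongs to) and `is_terminal`.
#' @export
extract_segments <- function(morph, neurite_filter = "axon") {
  stopifnot(inherits(morph, "morphology"))
  codes <- filter_codes(neurite_filter)
  nd <- morph$nodes
  in_f <- nd$structure %in% codes
  kids <- children_of(nd)
  pid <- match(nd$parent, nd$id)
  # trunk starts: filtered nodes whose parent is missing or not filtered
  starts <- which(in_f & (is.na(pid) | !in_f[pid]))
  segs <- list()
  # stack entries: (start_row, order, trunk)
  for (trunk_i in seq_along(starts)) {
    stack <- list(list(row = starts[trunk_i], order = 1L, from = NA_integer_))
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      # daughter segments include their branch point as first chain point so
      # that segment path lengths partition the total arbor length
      chain <- if (is.na(top$from)) top$row else c(top$from, top$row)
      repeat {
        ch <- kids[[chain[length(chain)]]]
        ch <- ch[in_f[ch]]
        if (length(ch) == 1L) {
          chain <- c(chain, ch)
        } else break
      }
      ch <- kids[[chain[length(chain)]]]
      ch <- ch[in_f[ch]]
      pts <- as.matrix(nd[chain, c("x", "y", "z")])
      path <- if (length(chain) > 1) {
        sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                          pts[-nrow(pts), , drop = FALSE])^2)))
      } else 0
      eucl <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
      segs[[length(segs) + 1L]] <- list(
        pts = pts, radii = nd$radius[chain], rows = chain,
        path_length = path, euclidean_length = eucl,
        order = top$order, trunk = trunk_i, is_terminal = length(ch) == 0L)
      for (c2 in ch) {
        stack[[length(stack) + 1L]] <- list(row = c2, order = top$order + 1L,
                                            from = chain[length(chain)])
      }
    }
  }
  segs
}

#' Horizontal and vertical extents of an arbor
#'
#' @param morph a [morphology()].
#' @param neurite_filter see [extract_segments()].
#' @return List with `h_extent` (x range, um), `v_extent` (y range, um),
#'   `hv_ratio` and `degenerate` flag (`TRUE` when the vertical extent is
#'   zero, in which case the ratio is `Inf` rather than silently dropped).
#' @export
compute_extents <- function(morph, neurite_filter = "axon") {
  nd <- morph$nodes
  sel <- nd$structure %in% filter_codes(neurite_filter)
  if (!any(sel)) stop("no nodes match the neurite filter")
  h <- diff(range(nd$x[sel]))
  v <- diff(range(nd$y[sel]))
  list(h_extent = h, v_extent = v,
       hv_ratio = if (v > 0) h / v else Inf,
       degenerate = v == 0)
}

#' Tortuosity of a segment
#'
#' Path length divided by the end-to-end chord.
#'
#' @param segment a segment from [extract_segments()].
#' @return Dimensionless tortuosity >= 1; `NA` with a warning for coincident
#'   endpoints.
#' @export
compute_tortuosity <- function(segment) {
  if (segment$path_length <= 0) stop("segment with zero path length")
  if (segment$euclidean_length == 0) {
    warning("segment with coincident endpoints; tortuosity undefined")
    return(NA_real_)
  }
  segment$path_length / segment$euclidean_length
}

angle_deg <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Branch angles at arbor bifurcations
#'
#' Per bifurcation: the local angle between the directions to the first
#' points of the two daughters; the maximum angle between the full daughter
#' chords (branch point to the daughter's next branch point or tip); the
#' planar angle between the daughter chords projected onto the bifurcation
#' plane (the least-squares plane through both daughters' points around the
#' branch point, so straight daughters give their true 3D angle and curved
#' daughters are flattened); and the local-spline angle, using daughter
#' directions smoothed over the first five points. Trifurcations use the
#' pairwise maximum. The cell value is the mean over bifurcations. These are
#' documented conventions; the proprietary definitions used by commercial
#' reconstruction software are not published.
#'
#' @param morph a [morphology()].
#' @param neurite_filter see [extract_segments()].
#' @return List with mean `maximum`, `planar`, `local`, `local_spline` angles
#'   in degrees and `n_bifurcations`.
#' @export
compute_branch_angles <- function(morph, neurite_filter = "axon") {
  segs <- extract_segments(morph, neurite_filter)
  if (length(segs) < 3) {
    return(list(maximum = NA_real_, planar = NA_real_, local = NA_real_,
                local_spline = NA_real_, n_bifurcations = 0L))
  }
  # group daughter segments by their branch point (first row of the segment
  # is the branch node itself for non-trunk segments)
  start_row <- vapply(segs, function(s) s$rows[1], integer(1))
  parent_end <- vapply(segs, function(s) s$rows[length(s$rows)], integer(1))
  loc <- pla <- mx <- spl <- numeric(0)
  for (b in unique(start_row[duplicated(start_row)])) {
    daughters <- segs[start_row == b & vapply(segs, function(s)
      length(s$rows) > 1, logical(1))]
    daughters <- daughters[vapply(daughters, function(s) s$rows[1] == b,
                                  logical(1))]
    if (length(daughters) < 2) next
    combs <- utils::combn(length(daughters), 2)
    a_loc <- a_pla <- a_max <- a_spl <- numeric(0)
    for (k in seq_len(ncol(combs))) {
      d1 <- daughters[[combs[1, k]]]; d2 <- daughters[[combs[2, k]]]
      u1 <- d1$pts[2, ] - d1$pts[1, ]; u2 <- d2$pts[2, ] - d2$pts[1, ]
      c1 <- d1$pts[nrow(d1$pts), ] - d1$pts[1, ]
      c2 <- d2$pts[nrow(d2$pts), ] - d2$pts[1, ]
      k1 <- min(5, nrow(d1$pts)); k2 <- min(5, nrow(d2$pts))
      s1 <- colMeans(d1$pts[2:k1, , drop = FALSE]) - d1$pts[1, ]
      s2 <- colMeans(d2$pts[2:k2, , drop = FALSE]) - d2$pts[1, ]
      a_loc <- c(a_loc, angle_deg(u1, u2))
      a_max <- c(a_max, angle_deg(c1, c2))
      a_spl <- c(a_spl, angle_deg(s1, s2))
      # bifurcation plane: least-squares plane through both daughters' points
      rel <- rbind(d1$pts[-1, , drop = FALSE], d2$pts[-1, , drop = FALSE])
      rel <- sweep(rel, 2, d1$pts[1, ])
      sv <- svd(rel, nu = 0, nv = 2)
      p1 <- as.numeric(c1 %*% sv$v)
      p2 <- as.numeric(c2 %*% sv$v)
      a_pla <- c(a_pla, angle_deg(c(p1, 0), c(p2, 0)))
    }
    # pairwise-max convention for multifurcations
    loc <- c(loc, max(a_loc, na.rm = TRUE))
    mx <- c(mx, max(a_max, na.rm = TRUE))
    spl <- c(spl, max(a_spl, na.rm = TRUE))
    if (length(a_pla)) pla <- c(pla, max(a_pla, na.rm = TRUE))
  }
  list(maximum = if (length(mx)) mean(mx) else NA_real_,
       planar = if (length(pla)) mean(pla) else NA_real_,
       local = if (length(loc)) mean(loc) else NA_real_,
       local_spline = if (length(spl)) mean(spl) else NA_real_,
       n_bifurcations = length(loc))
}

# edges of a filtered arbor: matrix with p (3), q (3), rp, rq, length
arbor_edges <- function(morph, codes) {
  nd <- morph$nodes
  in_f <- nd$structure %in% codes
  pid <- match(nd$parent, nd$id)
  child <- which(in_f & !is.na(pid) & in_f[ifelse(is.na(pid), 1L, pid)])
  if (length(child) == 0) {
    return(list(p = matrix(0, 0, 3), q = matrix(0, 0, 3),
                rp = numeric(0), rq = numeric(0), len = numeric(0)))
  }
  par <- pid[child]
  p <- as.matrix(nd[par, c("x", "y", "z")])
  q <- as.matrix(nd[child, c("x", "y", "z")])
  len <- sqrt(rowSums((q - p)^2))
  list(p = p, q = q, rp = nd$radius[par], rq = nd$radius[child], len = len)
}

#' Length-weighted spatial moments and arbor density
#'
#' First moment: the length-weighted centroid of the arbor, per axis, as an
#' offset from the soma. Second moment: the length-weighted standard
#' deviation per axis (computed exactly from per-edge closed forms). Density:
#' total arbor length divided by the volume of the axis-aligned bounding box
#' of the arbor points; when the box is degenerate (an axis extent below
#' `eps`), the largest-face area is used instead and the result flagged.
#'
#' @param morph a [morphology()].
#' @param neurite_filter see [extract_segments()].
#' @param eps degeneracy tolerance for box extents, um.
#' @return List with `moment1` (xyz, um), `moment2` (xyz, um), `density`
#'   (um per um^3, or um per um^2 when `planar` is `TRUE`), `total_length`
#'   and `planar` flag.
#' @export
compute_moments_density <- function(morph, neurite_filter = "axon", eps = 1e-9) {
  codes <- filter_codes(neurite_filter)
  ed <- arbor_edges(morph, codes)
  if (length(ed$len) == 0 || sum(ed$len) == 0) {
    stop("arbor has no edges under the given filter")
  }
  soma <- soma_center(morph)
  a <- sweep(ed$p, 2, soma)
  b <- sweep(ed$q, 2, soma)
  L <- sum(ed$len)
  m1 <- colSums(ed$len * (a + b) / 2) / L
  ex2 <- colSums(ed$len * (a^2 + a * b + b^2) / 3) / L
  m2 <- sqrt(pmax(0, ex2 - m1^2))
  nd <- morph$nodes
  sel <- nd$structure %in% codes
  ext <- c(diff(range(nd$x[sel])), diff(range(nd$y[sel])),
           diff(range(nd$z[sel])))
  planar <- any(ext < eps)
  denom <- if (planar) {
    f <- sort(ext, decreasing = TRUE)[1:2]
    # planar arbor: area-based density; linear arbor: extent-based
    if (f[2] < eps) {
      if (f[1] < eps) stop("arbor has no spatial extent")
      f[1]
    } else prod(f)
  } else prod(ext)
  list(moment1 = stats::setNames(m1, c("x", "y", "z")),
       moment2 = stats::setNames(m2, c("x", "y", "z")),
       density = L / denom, total_length = L, planar = planar)
}

#' Canonical names of the 44-feature morphometric battery
#'
#' @return Character vector of length 44, in the canonical ordering
#'   (soma, then dendritic, then axonal features).
#' @export
morphometric_feature_names <- function() {
  c("soma_csa",
    "basal_n_trunks", "basal_mean_trunk_diameter", "basal_n_segments",
    "basal_max_branch_order", "basal_max_path_length",
    "basal_max_radial_distance", "basal_max_degree", "basal_total_length",
    "basal_total_surface_area", "basal_total_volume",
    "basal_bif_mean_branch_length", "basal_horizontal_range",
    "basal_vertical_range",
    "dend_moment1_x", "dend_moment1_y", "dend_moment1_z",
    "dend_moment2_x", "dend_moment2_y", "dend_moment2_z",
    "dend_density", "dend_tortuosity", "dend_hv_ratio",
    "axon_mean_trunk_diameter", "axon_n_segments", "axon_max_branch_order",
    "axon_max_path_length", "axon_max_radial_distance", "axon_max_degree",
    "axon_total_length", "axon_total_surface_area", "axon_total_volume",
    "axon_bif_mean_branch_length", "axon_horizontal_range",
    "axon_vertical_range",
    "axon_moment1_x", "axon_moment1_y", "axon_moment1_z",
    "axon_moment2_x", "axon_moment2_y", "axon_moment2_z",
    "axon_density", "axon_tortuosity", "axon_hv_ratio")
}

# per-arbor feature block shared by dendrite and axon
arbor_features <- function(morph, codes) {
  nd <- morph$nodes
  segs <- extract_segments(morph, codes)
  if (length(segs) == 0) stop("empty arbor for structure code(s) ",
                              paste(codes, collapse = ","))
  ed <- arbor_edges(morph, codes)
  soma <- soma_center(morph)
  pid <- match(nd$parent, nd$id)
  in_f <- nd$structure %in% codes
  trunk_rows <- which(in_f & (is.na(pid) | !in_f[pid]))
  # path distance from soma per filtered node (parents precede children)
  xyz <- as.matrix(nd[, c("x", "y", "z")])
  pathd <- rep(NA_real_, nrow(nd))
  for (i in which(in_f)) {
    p <- pid[i]
    if (is.na(p) || !in_f[p]) {
      pathd[i] <- 0
    } else {
      pathd[i] <- pathd[p] + sqrt(sum((xyz[i, ] - xyz[p, ])^2))
    }
  }
  radial <- sqrt((nd$x - soma["x"])^2 + (nd$y - soma["y"])^2 +
                 (nd$z - soma["z"])^2)
  tips_per_trunk <- vapply(seq_along(trunk_rows), function(ti) {
    sum(vapply(segs, function(s) s$trunk == ti && s$is_terminal, logical(1)))
  }, numeric(1))
  rbar <- (ed$rp + ed$rq) / 2
  tort <- vapply(segs, function(s) {
    if (s$euclidean_length > 0 && s$path_length > 0)
      s$path_length / s$euclidean_length else NA_real_
  }, numeric(1))
  ext <- compute_extents(morph, codes)
  md <- compute_moments_density(morph, codes)
  list(
    n_trunks = length(trunk_rows),
    mean_trunk_diameter = mean(2 * nd$radius[trunk_rows]),
    n_segments = length(segs),
    max_branch_order = max(vapply(segs, `[[`, numeric(1), "order")),
    max_path_length = max(pathd, na.rm = TRUE),
    max_radial_distance = max(radial[in_f]),
    max_degree = max(tips_per_trunk),
    total_length = sum(ed$len),
    total_surface_area = sum(2 * pi * rbar * ed$len),
    total_volume = sum(pi * rbar^2 * ed$len),
    bif_mean_branch_length = mean(vapply(segs, `[[`, numeric(1),
                                         "path_length")),
    horizontal_range = ext$h_extent,
    vertical_range = ext$v_extent,
    moment1 = md$moment1, moment2 = md$moment2, density = md$density,
    tortuosity = mean(tort, na.rm = TRUE),
    hv_ratio = ext$hv_ratio
  )
}

soma_cross_section <- function(morph) {
  s <- morph$nodes[morph$nodes$structure == 1L, ]
  if (nrow(s) == 0) stop("no soma nodes")
  if (nrow(s) < 3) return(pi * max(s$radius)^2)
  # 2D contour projection: convex hull area in the x-y plane
  h <- grDevices::chull(s$x, s$y)
  if (length(h) < 3) return(pi * max(s$radius)^2)
  xs <- s$x[h]; ys <- s$y[h]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

#' Compute the full 44-feature morphometric vector of a cell
#'
#' Assembles the canonical battery ([morphometric_feature_names()]): soma
#' cross-sectional area, a dendritic block (trunks, segments, orders, path
#' and radial reach, degree, length/surface/volume, ranges, moments, density,
#' tortuosity, H/V ratio) and the analogous axonal block. Branch-angle means
#' for both arbors are attached alongside, and bouton density (markers per um
#' of axon) when axonal bouton markers are supplied.
#'
#' @param morph a [morphology()].
#' @param markers optional n x 3 matrix of bouton marker positions attributed
#'   to the axon (each must lie within `marker_tol` of an axon node).
#' @param marker_tol tolerance for marker-to-axon attribution, um.
#' @return A list of class `morphometric_vector`: `features` (named numeric,
#'   length 44), `angles` (dendrite and axon angle means), `bouton_density`
#'   (per um, `NA` without markers) and `cell_id`.
#' @export
compute_feature_vector <- function(morph, markers = NULL, marker_tol = 2) {
  dend <- arbor_features(morph, 3L)
  axon <- arbor_features(morph, 2L)
  f <- c(
    soma_csa = soma_cross_section(morph),
    basal_n_trunks = dend$n_trunks,
    basal_mean_trunk_diameter = dend$mean_trunk_diameter,
    basal_n_segments = dend$n_segments,
    basal_max_branch_order = dend$max_branch_order,
    basal_max_path_length = dend$max_path_length,
    basal_max_radial_distance = dend$max_radial_distance,
    basal_max_degree = dend$max_degree,
    basal_total_length = dend$total_length,
    basal_total_surface_area = dend$total_surface_area,
    basal_total_volume = dend$total_volume,
    basal_bif_mean_branch_length = dend$bif_mean_branch_length,
    basal_horizontal_range = dend$horizontal_range,
    basal_vertical_range = dend$vertical_range,
    dend_moment1_x = dend$moment1[["x"]],
    dend_moment1_y = dend$moment1[["y"]],
    dend_moment1_z = dend$moment1[["z"]],
    dend_moment2_x = dend$moment2[["x"]],
    dend_moment2_y = dend$moment2[["y"]],
    dend_moment2_z = dend$moment2[["z"]],
    dend_density = dend$density,
    dend_tortuosity = dend$tortuosity,
    dend_hv_ratio = dend$hv_ratio,
    axon_mean_trunk_diameter = axon$mean_trunk_diameter,
    axon_n_segments = axon$n_segments,
    axon_max_branch_order = axon$max_branch_order,
    axon_max_path_length = axon$max_path_length,
    axon_max_radial_distance = axon$max_radial_distance,
    axon_max_degree = axon$max_degree,
    axon_total_length = axon$total_length,
    axon_total_surface_area = axon$total_surface_area,
    axon_total_volume = axon$total_volume,
    axon_bif_mean_branch_length = axon$bif_mean_branch_length,
    axon_horizontal_range = axon$horizontal_range,
    axon_vertical_range = axon$vertical_range,
    axon_moment1_x = axon$moment1[["x"]],
    axon_moment1_y = axon$moment1[["y"]],
    axon_moment1_z = axon$moment1[["z"]],
    axon_moment2_x = axon$moment2[["x"]],
    axon_moment2_y = axon$moment2[["y"]],
    axon_moment2_z = axon$moment2[["z"]],
    axon_density = axon$density,
    axon_tortuosity = axon$tortuosity,
    axon_hv_ratio = axon$hv_ratio
  )
  stopifnot(identical(names(f), morphometric_feature_names()))
  bouton_density <- NA_real_
  if (!is.null(markers)) {
    markers <- as.matrix(markers)
    ax <- morph$nodes[morph$nodes$structure == 2L, c("x", "y", "z")]
    for (i in seq_len(nrow(markers))) {
      d2 <- (ax$x - markers[i, 1])^2 + (ax$y - markers[i, 2])^2 +
        (ax$z - markers[i, 3])^2
      if (min(d2) > marker_tol^2) {
        stop("bouton marker ", i, " lies > ", marker_tol,
             " um from every axon node")
      }
    }
    bouton_density <- nrow(markers) / axon$total_length
  }
  structure(
    list(features = f,
         angles = list(dendrite = compute_branch_angles(morph, 3L),
                       axon = compute_branch_angles(morph, 2L)),
         bouton_density = bouton_density,
         cell_id = morph$cell_id),
    class = "morphometric_vector"
  )
}

#' @export
print.morphometric_vector <- function(x, ...) {
  cat(sprintf("<morphometric_vector> %s: %d features\n", x$cell_id,
              length(x$features)))
  cat(sprintf("  axon length %.0f um (H %.0f x V %.0f), dendrite length %.0f um\n",
              x$features[["axon_total_length"]],
              x$features[["axon_horizontal_range"]],
              x$features[["axon_vertical_range"]],
              x$features[["basal_total_length"]]))
  invisible(x)
}

#' Morphometric feature table for a set of cells
#'
#' @param morphs list of [morphology()] objects (or a directory of SWC files).
#' @param shrinkage_measured_um optional measured slice thickness; when given,
#'   [shrinkage_correct()] is applied before feature extraction.
#' @return A data.frame with one row per cell (column `cell_id` plus the 44
#'   features).
#' @export
morphometry_table <- function(morphs, shrinkage_measured_um = NULL) {
  if (is.character(morphs)) {
    files <- list.files(morphs, pattern = "\\.swc$", full.names = TRUE)
    morphs <- lapply(files, read_swc)
  }
  rows <- lapply(morphs, function(m) {
    if (!is.null(shrinkage_measured_um)) {
      m <- shrinkage_correct(m, shrinkage_measured_um)
    }
    fv <- compute_feature_vector(m)
    cbind(data.frame(cell_id = fv$cell_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(fv$features)))
  })
  do.call(rbind, rows)
}
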