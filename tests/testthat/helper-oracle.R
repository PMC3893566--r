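# Independent naive morphometry oracle: recomputes every feature of the
# 44-feature battery by direct recursive traversal of the node table, sharing
# no code with the package implementation.

oracle_features <- function(morph) {
  nd <- morph$nodes
  pidx <- match(nd$parent, nd$id)
  soma_rows <- which(nd$structure == 1)
  soma <- c(mean(nd$x[soma_rows]), mean(nd$y[soma_rows]), mean(nd$z[soma_rows]))

  kids_of <- function(i) which(!is.na(pidx) & pidx == i)

  arbor <- function(code) {
    inf <- nd$structure == code
    trunks <- which(inf & (is.na(pidx) | !inf[pidx]))

    # edges within the arbor
    ch <- which(inf & !is.na(pidx) & inf[pidx])
    pa <- pidx[ch]
    elen <- sqrt((nd$x[ch] - nd$x[pa])^2 + (nd$y[ch] - nd$y[pa])^2 +
                 (nd$z[ch] - nd$z[pa])^2)
    rbar <- (nd$radius[ch] + nd$radius[pa]) / 2

    # recursive segment walk
    segments <- list()
    walk <- function(row, order, seg_start_row) {
      chain <- c(seg_start_row, row)
      repeat {
        k <- kids_of(chain[length(chain)])
        k <- k[inf[k]]
        if (length(k) == 1) chain <- c(chain, k) else break
      }
      last <- chain[length(chain)]
      pts <- cbind(nd$x[chain], nd$y[chain], nd$z[chain])
      pl <- 0
      for (i in seq_len(nrow(pts) - 1)) {
        pl <- pl + sqrt(sum((pts[i + 1, ] - pts[i, ])^2))
      }
      segments[[length(segments) + 1]] <<- list(
        order = order, path = pl,
        chord = sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2)),
        terminal = length(k[inf[k]]) == 0, start = chain[1])
      for (k2 in kids_of(last)) {
        if (inf[k2]) walk(k2, order + 1, last)
      }
    }
    # trunk segments have no preceding branch point: start chain at the trunk
    for (tr in trunks) {
      chain <- tr
      repeat {
        k <- kids_of(chain[length(chain)])
        k <- k[inf[k]]
        if (length(k) == 1) chain <- c(chain, k) else break
      }
      pts <- cbind(nd$x[chain], nd$y[chain], nd$z[chain])
      pl <- 0
      for (i in seq_len(nrow(pts) - 1)) {
        pl <- pl + sqrt(sum((pts[i + 1, ] - pts[i, ])^2))
      }
      k <- kids_of(chain[length(chain)]); k <- k[inf[k]]
      segments[[length(segments) + 1]] <- list(
        order = 1, path = pl,
        chord = sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2)),
        terminal = length(k) == 0, start = tr)
      for (k2 in k) walk(k2, 2, chain[length(chain)])
    }

    # path distance from trunk origin, recursively
    maxpath <- 0
    pd <- function(row, acc) {
      if (acc > maxpath) maxpath <<- acc
      for (k in kids_of(row)) {
        if (inf[k]) {
          step <- sqrt((nd$x[k] - nd$x[row])^2 + (nd$y[k] - nd$y[row])^2 +
                       (nd$z[k] - nd$z[row])^2)
          pd(k, acc + step)
        }
      }
    }
    for (tr in trunks) pd(tr, 0)

    # tips per trunk
    count_tips <- function(row) {
      k <- kids_of(row); k <- k[inf[k]]
      if (length(k) == 0) return(1)
      sum(vapply(k, count_tips, numeric(1)))
    }
    degrees <- vapply(trunks, count_tips, numeric(1))

    # moments by fine discretization of each edge
    step <- 0.1
    wsum <- 0; m1 <- c(0, 0, 0); m2raw <- c(0, 0, 0)
    for (e in seq_along(ch)) {
      p <- c(nd$x[pa[e]], nd$y[pa[e]], nd$z[pa[e]])
      q <- c(nd$x[ch[e]], nd$y[ch[e]], nd$z[ch[e]])
      L <- elen[e]
      if (L == 0) next
      nsub <- max(2, ceiling(L / step))
      tt <- (seq_len(nsub) - 0.5) / nsub
      w <- L / nsub
      for (ax in 1:3) {
        xs <- p[ax] + tt * (q[ax] - p[ax]) - soma[ax]
        m1[ax] <- m1[ax] + w * sum(xs)
        m2raw[ax] <- m2raw[ax] + w * sum(xs^2)
      }
      wsum <- wsum + L
    }
    m1 <- m1 / wsum
    m2 <- sqrt(pmax(0, m2raw / wsum - m1^2))

    xs <- nd$x[inf]; ys <- nd$y[inf]; zs <- nd$z[inf]
    ext <- c(diff(range(xs)), diff(range(ys)), diff(range(zs)))
    vol <- if (all(ext > 1e-9)) prod(ext) else
      prod(sort(ext, decreasing = TRUE)[1:2])
    radial <- sqrt((xs - soma[1])^2 + (ys - soma[2])^2 + (zs - soma[3])^2)
    torts <- vapply(segments, function(s)
      if (s$chord > 0 && s$path > 0) s$path / s$chord else NA_real_,
      numeric(1))
    list(
      n_trunks = length(trunks),
      mean_trunk_diameter = mean(2 * nd$radius[trunks]),
      n_segments = length(segments),
      max_order = max(vapply(segments, `[[`, numeric(1), "order")),
      max_path = maxpath,
      max_radial = max(radial),
      max_degree = max(degrees),
      total_length = sum(elen),
      surface = sum(2 * pi * rbar * elen),
      volume = sum(pi * rbar^2 * elen),
      mean_seg_len = mean(vapply(segments, `[[`, numeric(1), "path")),
      h_range = ext[1], v_range = ext[2],
      m1 = m1, m2 = m2,
      density = sum(elen) / vol,
      tortuosity = mean(torts, na.rm = TRUE),
      hv = ext[1] / ext[2]
    )
  }

  d <- arbor(3); a <- arbor(2)
  soma_area <- if (length(soma_rows) >= 3) {
    h <- grDevices::chull(nd$x[soma_rows], nd$y[soma_rows])
    if (length(h) >= 3) {
      xs <- nd$x[soma_rows][h]; ys <- nd$y[soma_rows][h]
      abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
    } else pi * max(nd$radius[soma_rows])^2
  } else pi * max(nd$radius[soma_rows])^2
  c(soma_csa = soma_area,
    basal_n_trunks = d$n_trunks,
    basal_mean_trunk_diameter = d$mean_trunk_diameter,
    basal_n_segments = d$n_segments,
    basal_max_branch_order = d$max_order,
    basal_max_path_length = d$max_path,
    basal_max_radial_distance = d$max_radial,
    basal_max_degree = d$max_degree,
    basal_total_length = d$total_length,
    basal_total_surface_area = d$surface,
    basal_total_volume = d$volume,
    basal_bif_mean_branch_length = d$mean_seg_len,
    basal_horizontal_range = d$h_range,
    basal_vertical_range = d$v_range,
    dend_moment1_x = d$m1[1], dend_moment1_y = d$m1[2],
    dend_moment1_z = d$m1[3],
    dend_moment2_x = d$m2[1], dend_moment2_y = d$m2[2],
    dend_moment2_z = d$m2[3],
    dend_density = d$density, dend_tortuosity = d$tortuosity,
    dend_hv_ratio = d$hv,
    axon_mean_trunk_diameter = a$mean_trunk_diameter,
    axon_n_segments = a$n_segments,
    axon_max_branch_order = a$max_order,
    axon_max_path_length = a$max_path,
    axon_max_radial_distance = a$max_radial,
    axon_max_degree = a$max_degree,
    axon_total_length = a$total_length,
    axon_total_surface_area = a$surface,
    axon_total_volume = a$volume,
    axon_bif_mean_branch_length = a$mean_seg_len,
    axon_horizontal_range = a$h_range,
    axon_vertical_range = a$v_range,
    axon_moment1_x = a$m1[1], axon_moment1_y = a$m1[2],
    axon_moment1_z = a$m1[3],
    axon_moment2_x = a$m2[1], axon_moment2_y = a$m2[2],
    axon_moment2_z = a$m2[3],
    axon_density = a$density, axon_tortuosity = a$tortuosity,
    axon_hv_ratio = a$hv)
}
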