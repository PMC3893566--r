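#' Connection probability with exact binomial confidence interval
#'
#' In directed mode each ordered direction of a probed pair counts as one
#' test; in undirected mode (gap junctions) each unordered pair counts once.
#'
#' @param records data.frame of probe records with columns `direction`
#'   (`"1->2"`, `"2->1"`, `"gj"`), `tested`, `connected`
#'   (e.g. from [generate_pair_population()]), or a list with `n_connected`
#'   and `n_tested`.
#' @param mode `"directed"` (synaptic) or `"undirected"` (gap junction).
#' @param conf_level confidence level of the Clopper-Pearson interval.
#' @return A list of class `connection_probability`: `p`, `percent`,
#'   `n_connected`, `n_tested`, `ci` (length-2).
#' @export
connection_probability <- function(records, mode = c("directed", "undirected"),
                                   conf_level = 0.95) {
  mode <- match.arg(mode)
  if (is.data.frame(records)) {
    sel <- if (mode == "directed") records$direction %in% c("1->2", "2->1")
           else records$direction == "gj"
    rec <- records[sel & records$tested, ]
    n_tested <- nrow(rec)
    n_connected <- sum(rec$connected)
  } else {
    n_tested <- records$n_tested
    n_connected <- records$n_connected
  }
  if (is.null(n_tested) || n_tested < 1) stop("zero tested records")
  bt <- stats::binom.test(n_connected, n_tested, conf.level = conf_level)
  structure(list(p = n_connected / n_tested,
                 percent = 100 * n_connected / n_tested,
                 n_connected = n_connected, n_tested = n_tested,
                 ci = unname(bt$conf.int)),
            class = "connection_probability")
}

#' @export
print.connection_probability <- function(x, ...) {
  cat(sprintf("<connection_probability> %d/%d = %.2f%% (95%% CI %.2f-%.2f%%)\n",
              x$n_connected, x$n_tested, x$percent,
              100 * x$ci[1], 100 * x$ci[2]))
  invisible(x)
}

#' Cross-tabulate electrophysiological and morphological types
#'
#' Joins the two classifications on cell id and reports the contingency
#' table, exact marginal and joint fractions, and the most frequent
#' morpho-electrical combination.
#'
#' @param etypes data.frame with `cell_id`, `label` (firing type).
#' @param mtypes data.frame with `cell_id`, `label` (morphological type).
#' @return A list of class `me_crosstab`: `table` (m-type x e-type counts),
#'   `joint_percent`, `e_marginal_percent`, `m_marginal_percent`, `n_cells`,
#'   `most_common` (list with `mtype`, `etype`, `count`, `percent`).
#' @export
crosstab_me_types <- function(etypes, mtypes) {
  common <- intersect(etypes$cell_id, mtypes$cell_id)
  if (length(common) == 0) stop("no cells in common between the two tables")
  e <- etypes$label[match(common, etypes$cell_id)]
  m <- mtypes$label[match(common, mtypes$cell_id)]
  tab <- table(mtype = m, etype = e)
  n <- length(common)
  joint <- 100 * tab / n
  top <- which(tab == max(tab), arr.ind = TRUE)[1, ]
  structure(list(
    table = tab, joint_percent = joint,
    e_marginal_percent = 100 * margin.table(tab, 2) / n,
    m_marginal_percent = 100 * margin.table(tab, 1) / n,
    n_cells = n,
    most_common = list(mtype = rownames(tab)[top[1]],
                       etype = colnames(tab)[top[2]],
                       count = as.integer(max(tab)),
                       percent = 100 * max(tab) / n)),
    class = "me_crosstab")
}

#' @export
print.me_crosstab <- function(x, ...) {
  cat(sprintf("<me_crosstab> %d cells; most common: %s-%s (%d, %.1f%%)\n",
              x$n_cells, x$most_common$mtype, x$most_common$etype,
              x$most_common$count, x$most_common$percent))
  print(x$table)
  invisible(x)
}

#' Detect putative synaptic contacts between two morphologies
#'
#' A putative contact ("close apposition") is any presynaptic axon point
#' lying within `distance_threshold` (3D) of a postsynaptic soma or dendrite
#' point with a slice-depth difference of at most `z_tolerance` (the "same
#' focal plane" criterion). Contacts closer than `dedup_um` to an already
#' accepted contact are deduplicated. Both morphologies must be in a common
#' coordinate frame; disjoint arbors simply yield an empty map.
#'
#' @param pre_morph presynaptic [morphology()] (its axon is used).
#' @param post_morph postsynaptic [morphology()] (soma + dendrites used).
#' @param distance_threshold apposition distance, um.
#' @param z_tolerance focal-plane tolerance, um.
#' @param dedup_um deduplication radius, um.
#' @return A list of class `contact_map`: `contacts` (data.frame `x`, `y`,
#'   `z`, `target_compartment`, `distance_um`), `n_contacts`,
#'   `fraction_somatic`, `fraction_dendritic`.
#' @export
detect_appositions <- function(pre_morph, post_morph, distance_threshold = 3,
                               z_tolerance = 1, dedup_um = 2) {
  pre <- pre_morph$nodes[pre_morph$nodes$structure == 2L, ]
  post <- post_morph$nodes[post_morph$nodes$structure %in% c(1L, 3L), ]
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      target_compartment = character(0),
                      distance_um = numeric(0), stringsAsFactors = FALSE)
  if (nrow(pre) == 0 || nrow(post) == 0) {
    return(structure(list(contacts = empty, n_contacts = 0L,
                          fraction_somatic = NA_real_,
                          fraction_dendritic = NA_real_),
                     class = "contact_map"))
  }
  hits <- list()
  # chunk the distance computation to bound memory on large arbors
  chunk <- max(1L, floor(2e6 / nrow(post)))
  for (start in seq(1L, nrow(pre), by = chunk)) {
    ix <- start:min(start + chunk - 1L, nrow(pre))
    dz <- abs(outer(pre$z[ix], post$z, "-"))
    d2 <- outer(pre$x[ix], post$x, "-")^2 +
      outer(pre$y[ix], post$y, "-")^2 + dz^2
    ok <- which(d2 <= distance_threshold^2 & dz <= z_tolerance,
                arr.ind = TRUE)
    if (nrow(ok)) {
      hits[[length(hits) + 1L]] <- data.frame(
        pre_row = ix[ok[, 1]], post_row = ok[, 2],
        distance_um = sqrt(d2[ok]))
    }
  }
  if (length(hits) == 0) {
    return(structure(list(contacts = empty, n_contacts = 0L,
                          fraction_somatic = NA_real_,
                          fraction_dendritic = NA_real_),
                     class = "contact_map"))
  }
  h <- do.call(rbind, hits)
  h <- h[order(h$distance_um), ]
  pos <- cbind((pre$x[h$pre_row] + post$x[h$post_row]) / 2,
               (pre$y[h$pre_row] + post$y[h$post_row]) / 2,
               (pre$z[h$pre_row] + post$z[h$post_row]) / 2)
  keep <- integer(0)
  for (i in seq_len(nrow(h))) {
    if (length(keep) == 0 ||
        min(sqrt(colSums((t(pos[keep, , drop = FALSE]) - pos[i, ])^2))) >=
          dedup_um) {
      keep <- c(keep, i)
    }
  }
  comp <- ifelse(post$structure[h$post_row[keep]] == 1L, "soma", "dendrite")
  contacts <- data.frame(x = pos[keep, 1], y = pos[keep, 2], z = pos[keep, 3],
                         target_compartment = comp,
                         distance_um = h$distance_um[keep],
                         stringsAsFactors = FALSE)
  structure(list(contacts = contacts, n_contacts = nrow(contacts),
                 fraction_somatic = mean(comp == "soma"),
                 fraction_dendritic = mean(comp == "dendrite")),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d putative contacts (%.0f%% somatic)\n",
              x$n_contacts, 100 * x$fraction_somatic))
  invisible(x)
}

#' Nernst reversal potential
#'
#' `E = (RT / zF) ln(c_out / c_in)`, in mV. With the standard recording
#' solutions (aCSF outside, potassium-gluconate pipette solution inside) this
#' gives a chloride reversal near -69 mV and a potassium reversal near
#' -102 mV at 34 degrees C.
#'
#' @param ion_valence signed valence z (e.g. +1 for K+, -1 for Cl-).
#' @param c_in,c_out inside/outside concentrations, mM (> 0).
#' @param temperature_c temperature in degrees Celsius.
#' @return Reversal potential in mV.
#' @export
nernst <- function(ion_valence, c_in, c_out, temperature_c = 34) {
  if (c_in <= 0 || c_out <= 0) stop("concentrations must be > 0")
  if (ion_valence == 0) stop("valence must be non-zero")
  if (temperature_c < -273.15) stop("temperature below absolute zero")
  R <- 8.314462618   # J / (mol K)
  F <- 96485.33212   # C / mol
  T <- temperature_c + 273.15
  1000 * R * T / (ion_valence * F) * log(c_out / c_in)
}

#' Assemble a structured analysis report
#'
#' Bundles per-stage outputs with a reproducibility block (seed, package
#' version, a stable hash of the configuration) and serializes to JSON with
#' stable key order, so identical inputs give byte-identical reports.
#'
#' @param stages named list of stage outputs (any JSON-serializable
#'   structures); stages set to `NULL` are reported as gaps.
#' @param seed the seed the run used.
#' @param config optional configuration list included and hashed.
#' @param path optional file path; when given the JSON is written there.
#' @return The report list (class `l1_report`), invisibly when written.
#' @export
build_report <- function(stages, seed = NA_integer_, config = list(),
                         path = NULL) {
  if (length(stages) == 0) stop("at least one stage output required")
  stages <- stages[order(names(stages))]
  gaps <- names(stages)[vapply(stages, is.null, logical(1))]
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  report <- list(
    reproducibility = list(
      seed = seed,
      package_version = as.character(utils::packageVersion("l1census")),
      config = config,
      config_hash = sprintf("%08x", sum(utf8ToInt(as.character(cfg_json)) *
                                          (seq_len(nchar(cfg_json)) %% 97 + 1)) %% 0xFFFFFFFF),
      missing_stages = gaps
    ),
    stages = stages
  )
  class(report) <- "l1_report"
  if (!is.null(path)) {
    json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 12,
                             null = "null", force = TRUE, pretty = TRUE)
    writeLines(json, path)
    return(invisible(report))
  }
  report
}

#' @export
print.l1_report <- function(x, ...) {
  cat(sprintf("<l1_report> seed %s; stages: %s\n",
              x$reproducibility$seed,
              paste(names(x$stages), collapse = ", ")))
  if (length(x$reproducibility$missing_stages)) {
    cat("  gaps:", paste(x$reproducibility$missing_stages, collapse = ", "),
        "\n")
  }
  invisible(x)
}
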