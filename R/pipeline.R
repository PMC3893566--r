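#' Run the full synthetic census pipeline
#'
#' End-to-end demonstration on generated data: synthesizes cells of every
#' firing type and classifies their traces; synthesizes morphologies of every
#' morphological class and classifies... extracts their feature batteries;
#' synthesizes one paired recording per receptor class and classifies them;
#' generates a probed pair population and estimates connection probabilities;
#' and assembles everything into a report.
#'
#' @param seed integer master seed.
#' @param n_per_etype cells generated per firing type.
#' @param n_per_mtype morphologies generated per morphological class.
#' @param n_pairs probed pairs in the connectivity population.
#' @param p_syn_directed,p_gj ground-truth connection probabilities of the
#'   synthetic population (defaults: the reported layer-1 values).
#' @param out optional path for the JSON report.
#' @return An `l1_report` (see [build_report()]).
#' @export
run_l1_demo <- function(seed = 1, n_per_etype = 2, n_per_mtype = 1,
                        n_pairs = 1568, p_syn_directed = 248 / 3136,
                        p_gj = 82 / 1568, out = NULL) {
  etypes <- c("cAC", "cNAC", "bNAC_burst", "bNAC_doublet", "cSTUT", "cIR")
  e_rows <- list()
  for (et in etypes) {
    for (i in seq_len(n_per_etype)) {
      tr <- generate_spike_response(etype_gen_defaults(et, seed = seed + 13 * i))
      lab <- classify_etype(detect_spikes(tr))
      e_rows[[length(e_rows) + 1L]] <- data.frame(
        cell_id = tr$meta$cell_id, true_type = et, label = lab$label,
        subtype = lab$subtype, stringsAsFactors = FALSE)
    }
  }
  e_tab <- do.call(rbind, e_rows)
  e_counts <- table(e_tab$label)

  mtypes <- c("NGC-DA", "NGC-SA", "HAC", "DAC", "LAC", "SAC")
  m_rows <- list()
  for (mt in mtypes) {
    for (i in seq_len(n_per_mtype)) {
      m <- generate_morphology(mtype_gen_defaults(mt, seed = seed + 7 * i))
      fv <- compute_feature_vector(m)
      m_rows[[length(m_rows) + 1L]] <- data.frame(
        cell_id = m$cell_id, true_type = mt,
        axon_length = fv$features[["axon_total_length"]],
        axon_hv = fv$features[["axon_hv_ratio"]],
        stringsAsFactors = FALSE)
    }
  }
  m_tab <- do.call(rbind, m_rows)

  receptor_truth <- c("GABA_A", "GABA_B", "GABA_AB")
  train <- seq(0, by = 25, length.out = 15) + 100  # 40 Hz, 15 APs
  rec_rows <- lapply(receptor_truth, function(rc) {
    sp <- synapse_gen_spec(rc, noise_sd = 0.02, rundown_rate = 0, seed = seed)
    f1 <- extract_ipsp(generate_paired_recording(sp, 100))
    ft <- extract_ipsp(generate_paired_recording(sp, train))
    data.frame(true_receptor = rc,
               label = classify_receptor(f1, ft)$label,
               stringsAsFactors = FALSE)
  })
  rec_tab <- do.call(rbind, rec_rows)

  pop <- generate_pair_population(n_pairs, p_syn_directed, p_gj, seed = seed)
  p_syn <- connection_probability(pop, "directed")
  p_gj_est <- connection_probability(pop, "undirected")

  build_report(
    stages = list(
      etype_counts = as.list(e_counts),
      etype_accuracy = mean(e_tab$label ==
                              ifelse(startsWith(e_tab$true_type, "bNAC"),
                                     "bNAC", e_tab$true_type)),
      morphology = list(n_cells = nrow(m_tab),
                        mean_axon_length_um = mean(m_tab$axon_length)),
      receptor_labels = stats::setNames(as.list(rec_tab$label),
                                        rec_tab$true_receptor),
      connectivity = list(
        synaptic_percent = p_syn$percent,
        gap_junction_percent = p_gj_est$percent,
        n_pairs = n_pairs),
      reversal_potentials_mv = list(
        chloride = nernst(-1, 10, 133.5, 34),
        potassium = nernst(+1, 120, 2.5, 34))
    ),
    seed = seed,
    config = list(n_per_etype = n_per_etype, n_per_mtype = n_per_mtype,
                  n_pairs = n_pairs, p_syn_directed = p_syn_directed,
                  p_gj = p_gj),
    path = out
  )
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions, used by the `l1census`
#' executable script. Subcommands: `demo` (full synthetic pipeline; flags
#' `--seed`, `--out`), `nernst` (flags `--ion K|Cl`, `--in`, `--out-conc`,
#' `--temp`), `etype` (`classify <dir>` of columnar trace files).
#'
#' @param argv character vector of command-line arguments.
#' @return Exit status (0 ok, 2 usage error), invisibly.
#' @export
l1c_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: l1census <demo|nernst|etype> [options]\n",
        "  demo   --seed <int> [--out report.json]\n",
        "  nernst --ion <K|Cl> --in <mM> --out-conc <mM> [--temp <C>]\n",
        "  etype  classify <trace-dir>\n", sep = "")
    invisible(2L)
  }
  getopt <- function(flag, default = NULL) {
    i <- which(argv == flag)
    if (length(i) == 1 && i < length(argv)) argv[i + 1] else default
  }
  if (length(argv) < 1) return(usage())
  cmd <- argv[1]
  if (cmd == "demo") {
    seed <- as.integer(getopt("--seed", "1"))
    rep <- run_l1_demo(seed = seed, out = getopt("--out"))
    print(rep)
    return(invisible(0L))
  }
  if (cmd == "nernst") {
    ion <- getopt("--ion")
    if (is.null(ion) || !ion %in% c("K", "Cl")) return(usage())
    z <- if (ion == "K") 1 else -1
    cin <- as.numeric(getopt("--in"))
    cout <- as.numeric(getopt("--out-conc"))
    if (is.na(cin) || is.na(cout)) return(usage())
    e <- nernst(z, cin, cout, as.numeric(getopt("--temp", "34")))
    cat(sprintf("E_%s = %.1f mV\n", ion, e))
    return(invisible(0L))
  }
  if (cmd == "etype") {
    if (length(argv) < 3 || argv[2] != "classify" || !dir.exists(argv[3])) {
      return(usage())
    }
    tab <- classify_etype_batch(argv[3])
    utils::write.table(tab, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(0L))
  }
  usage()
}
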