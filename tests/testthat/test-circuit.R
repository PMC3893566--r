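test_that("connection probabilities are exact count ratios with binomial CIs", {
  p <- connection_probability(list(n_connected = 82, n_tested = 1568))
  expect_equal(p$percent, 100 * 82 / 1568)
  expect_equal(round(p$percent, 1), 5.2)
  p2 <- connection_probability(list(n_connected = 248, n_tested = 3136))
  expect_equal(round(p2$percent, 1), 7.9)
  # zero connected: one-sided interval starting at 0
  p0 <- connection_probability(list(n_connected = 0, n_tested = 50))
  expect_equal(p0$p, 0)
  expect_equal(p0$ci[1], 0)
  expect_gt(p0$ci[2], 0)
  expect_error(connection_probability(list(n_connected = 0, n_tested = 0)),
               "zero tested")
})

test_that("probability estimates equal brute-force ratios on record tables", {
  pop <- generate_pair_population(300, 0.1, 0.05, seed = 1)
  est <- connection_probability(pop, "directed")
  brute <- sum(pop$connected[pop$direction != "gj"]) / (2 * 300)
  expect_equal(est$p, brute)
})

test_that("the confidence interval covers the truth at the nominal rate", {
  p_true <- 0.0523
  cover <- vapply(1:200, function(s) {
    pop <- generate_pair_population(1568, 0.079, p_true, seed = s)
    ci <- connection_probability(pop, "undirected")$ci
    p_true >= ci[1] && p_true <= ci[2]
  }, logical(1))
  # exact (Clopper-Pearson) intervals are conservative: coverage >= nominal
  # within binomial error of the 200-trial estimate
  expect_gte(mean(cover), 0.93)
})

test_that("morpho-electrical cross-tabulation reports counts and fractions", {
  et <- data.frame(cell_id = paste0("c", 1:38),
                   label = c(rep("cNAC", 28), rep("cAC", 6), rep("bNAC", 4)))
  mt <- data.frame(cell_id = paste0("c", 1:38),
                   label = c(rep("NGC-DA", 7), rep("HAC", 7),
                             rep("LAC", 7), rep("NGC-SA", 7),
                             rep("DAC", 6), rep("SAC", 4)))
  ct <- crosstab_me_types(et, mt)
  expect_equal(ct$n_cells, 38L)
  expect_equal(round(ct$most_common$percent, 1), 18.4)
  expect_equal(round(unname(ct$e_marginal_percent["cNAC"]), 1), 73.7)
  expect_equal(ct$most_common$count, 7L)

  single <- data.frame(cell_id = "c1", label = "cNAC")
  sm <- data.frame(cell_id = "c1", label = "HAC")
  cs <- crosstab_me_types(single, sm)
  expect_equal(cs$most_common$percent, 100)
  expect_error(crosstab_me_types(single,
                                 data.frame(cell_id = "zz", label = "HAC")),
               "common")
})

test_that("apposition detection finds constructed contacts and is monotone", {
  # presynaptic axon passing 1 um from a postsynaptic dendrite
  pre <- morphology(data.frame(
    id = 1:4, parent = c(-1, 1, 2, 3), structure = c(1, 2, 2, 2),
    x = c(-30, -10, 0, 10), y = c(1, 1, 1, 1), z = 0,
    radius = c(5, 0.3, 0.3, 0.3)), cell_id = "pre")
  post <- morphology(data.frame(
    id = 1:4, parent = c(-1, 1, 2, 3), structure = c(1, 3, 3, 3),
    x = c(30, 10, 0, -10), y = 0, z = 0,
    radius = c(5, 0.5, 0.5, 0.5)), cell_id = "post")
  cm <- detect_appositions(pre, post, distance_threshold = 3, z_tolerance = 1)
  expect_gte(cm$n_contacts, 1L)
  expect_true(all(cm$contacts$target_compartment == "dendrite"))

  # parallel neurites 50 um apart: nothing
  far <- post
  far$nodes$y <- far$nodes$y + 50
  expect_equal(detect_appositions(pre, far, 3, 1)$n_contacts, 0L)

  # monotone in the distance threshold
  n3 <- detect_appositions(pre, post, 3, 5)$n_contacts
  n8 <- detect_appositions(pre, post, 8, 5)$n_contacts
  expect_gte(n8, n3)
})

test_that("staged pairs report somatic and dendritic contact fractions", {
  # 9 contact sites: 4 on the soma, 5 on dendrites, spaced > 2 um apart
  soma_pts <- data.frame(id = 1:5, parent = c(-1, 1, 1, 1, 1), structure = 1,
                         x = c(0, 3, -3, 0, 0), y = c(0, 0, 0, 3, -3), z = 0,
                         radius = 4)
  dend_pts <- data.frame(id = 6:11, parent = c(1, 6, 7, 8, 9, 10),
                         structure = 3,
                         x = c(10, 20, 30, 40, 50, 60), y = 0, z = 0,
                         radius = 0.5)
  post <- morphology(rbind(soma_pts, dend_pts), cell_id = "post")
  # presynaptic axon points 1 um (z) above 4 soma points and 5 dendrite points
  targets <- rbind(
    cbind(c(3, -3, 0, 0), c(0, 0, 3, -3)),       # somatic
    cbind(c(20, 30, 40, 50, 60), c(0, 0, 0, 0, 0))) # dendritic
  pre_nodes <- data.frame(
    id = 1:10, parent = c(-1, 1:9), structure = c(1, rep(2, 9)),
    x = c(-40, targets[, 1]), y = c(0, targets[, 2]),
    z = c(0, rep(0.8, 9)), radius = c(5, rep(0.3, 9)))
  pre <- morphology(pre_nodes, cell_id = "pre")
  cm <- detect_appositions(pre, post, distance_threshold = 1.5,
                           z_tolerance = 1)
  expect_equal(cm$n_contacts, 9L)
  expect_equal(cm$fraction_somatic, 4 / 9, tolerance = 1e-9)
  expect_equal(cm$fraction_dendritic, 5 / 9, tolerance = 1e-9)
})

test_that("Nernst potentials satisfy identity and antisymmetry", {
  expect_equal(nernst(1, 10, 10, 34), 0)
  expect_equal(nernst(1, 5, 50, 34), -nernst(1, 50, 5, 34), tolerance = 1e-12)
  expect_equal(nernst(-1, 5, 50, 34), -nernst(1, 5, 50, 34), tolerance = 1e-12)
  expect_error(nernst(1, 0, 10), "concentrations")
  expect_error(nernst(0, 10, 10), "valence")
})

test_that("reports are stable and mark missing stages", {
  st <- list(b_stage = list(x = 1), a_stage = NULL)
  path1 <- withr::local_tempfile(fileext = ".json")
  path2 <- withr::local_tempfile(fileext = ".json")
  build_report(st, seed = 3, config = list(k = 2), path = path1)
  build_report(st, seed = 3, config = list(k = 2), path = path2)
  expect_identical(readLines(path1), readLines(path2))
  rep <- build_report(st, seed = 3)
  expect_equal(rep$reproducibility$missing_stages, "a_stage")
  expect_identical(names(rep$stages), c("a_stage", "b_stage"))
})
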