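test_that("z-normalization centres and scales; constant columns are dropped", {
  x <- cbind(a = c(1, 3), b = c(5, 5))
  expect_warning(z <- znormalize(feature_table(x)), "constant")
  expect_equal(dim(z$values), c(2L, 1L))
  expect_equal(z$values[, "a"], c(-1, 1) / sqrt(2), tolerance = 1e-12,
               ignore_attr = TRUE)

  set.seed(1)
  x <- matrix(rnorm(30 * 5, mean = 10, sd = 4), 30, 5)
  z <- znormalize(feature_table(x))
  expect_true(all(abs(colMeans(z$values)) < 1e-12))
  expect_equal(unname(apply(z$values, 2, sd)), rep(1, 5), tolerance = 1e-12)
})

test_that("outlier flagging reports the offending features and magnitudes", {
  set.seed(2)
  x <- matrix(rnorm(50 * 10), 50, 10)
  x <- scale(x)
  x[7, 3] <- 8.93
  ft <- feature_table(x)
  flags <- flag_outliers(ft, sd_limit = 2)
  expect_true(ft$cell_ids[7] %in% flags$cell_id)
  expect_equal(max(flags$max_z), 8.93, tolerance = 1e-9)
  # all-zero table: nothing flagged
  expect_equal(nrow(flag_outliers(feature_table(matrix(0, 10, 5)))), 0L)
})

test_that("flag fraction on standard-normal cells matches the closed form", {
  set.seed(3)
  p <- 42
  x <- matrix(rnorm(1000 * p), 1000, p)
  frac <- nrow(flag_outliers(feature_table(x), sd_limit = 2)) / 1000
  expected <- 1 - (pnorm(2) - pnorm(-2))^p
  expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / 1000))
})

test_that("feature power ranks discriminative features by variance ratio", {
  labels <- rep(c("a", "b"), each = 20)
  # identical across classes -> ratio 0; disjoint supports -> ratio 1
  x <- cbind(flat = rep(1:20, 2),
             split = c(rep(0, 20), rep(10, 20)))
  fp <- feature_power(feature_table(x, labels = labels))
  expect_equal(fp$var_ratio[fp$feature == "flat"], 0, tolerance = 1e-12)
  expect_equal(fp$var_ratio[fp$feature == "split"], 1, tolerance = 1e-12)
  expect_equal(fp$variance[fp$feature == "split"], 0, tolerance = 1e-12)
  expect_equal(fp$feature[1], "split")  # ranked first
})

test_that("two-class variance ratio matches the analytic effect-size form", {
  # balanced two-class shift of d SDs: eta^2 -> d^2 / (d^2 + 4)
  set.seed(4)
  d <- 1.5
  n <- 4000
  x <- cbind(f = c(rnorm(n), rnorm(n, d)))
  fp <- feature_power(feature_table(x, labels = rep(c("a", "b"), each = n)))
  expect_equal(fp$var_ratio, d^2 / (d^2 + 4), tolerance = 0.05)
})

test_that("PCA fractions and components behave as contracted", {
  set.seed(5)
  # isotropic 2D cloud: fractions about half each
  x <- matrix(rnorm(4000 * 2), 4000, 2)
  p <- run_pca(feature_table(x))
  expect_equal(p$explained_variance_fractions[1], 0.5, tolerance = 0.05)
  expect_equal(sum(p$explained_variance_fractions), 1, tolerance = 1e-9)
  # rank-1 data: first component carries everything
  u <- rnorm(50)
  x1 <- cbind(u, 2 * u, -u)
  p1 <- run_pca(feature_table(x1))
  expect_equal(p1$explained_variance_fractions[1], 1, tolerance = 1e-9)
  # eigen-decomposition oracle on a random matrix
  x <- matrix(rnorm(30 * 10), 30, 10)
  p <- run_pca(feature_table(x))
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  expect_equal(p$sdev^2, ev$values, tolerance = 1e-8)
  expect_equal(abs(diag(t(p$components) %*% ev$vectors)), rep(1, 10),
               tolerance = 1e-8)
  # orthonormality
  expect_equal(t(p$components) %*% p$components, diag(10), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("LDA separates separated classes and matches the Fisher closed form", {
  set.seed(6)
  x <- rbind(matrix(rnorm(40 * 3), 40, 3),
             matrix(rnorm(40 * 3, mean = 8), 40, 3))
  labels <- rep(c("a", "b"), each = 40)
  fit <- run_lda(feature_table(x, labels = labels))
  pred_means <- fit$class_means
  proj <- fit$projections
  assigned <- ifelse(abs(proj - pred_means[1]) < abs(proj - pred_means[2]),
                     "a", "b")
  expect_equal(mean(assigned == labels), 1.0)

  # two-class data: weight direction equals the Fisher closed form
  # w proportional to Sw^-1 (mu_b - mu_a), up to sign and scale
  x2 <- rbind(matrix(rnorm(30 * 2, sd = 2), 30, 2),
              sweep(matrix(rnorm(30 * 2, sd = 2), 30, 2), 2, c(3, -1), "+"))
  l2 <- rep(c("a", "b"), each = 30)
  fit2 <- run_lda(feature_table(x2, labels = l2))
  sw <- (cov(x2[1:30, ]) * 29 + cov(x2[31:60, ]) * 29) / 58
  w_cf <- solve(sw, colMeans(x2[31:60, ]) - colMeans(x2[1:30, ]))
  u1 <- fit2$weight_vectors[, 1] / sqrt(sum(fit2$weight_vectors[, 1]^2))
  u2 <- w_cf / sqrt(sum(w_cf^2))
  expect_lt(min(sum((u1 - u2)^2), sum((u1 + u2)^2)), 1e-9)
})

test_that("singular within-class scatter falls back to ridge regularization", {
  set.seed(7)
  x <- matrix(rnorm(10 * 20), 10, 20)  # more features than cells
  labels <- rep(c("a", "b"), each = 5)
  expect_message(fit <- run_lda(feature_table(x, labels = labels)),
                 "regulariz")
  expect_true(fit$regularized)
})

test_that("cross-validated accuracy is near chance under shuffled labels", {
  set.seed(8)
  x <- rbind(matrix(rnorm(30 * 4), 30, 4),
             matrix(rnorm(30 * 4, mean = 6), 30, 4))
  labels <- rep(c("a", "b"), each = 30)
  shuffled <- sample(labels)
  r <- suppressMessages(
    crossvalidate_randomized(feature_table(x, labels = shuffled),
                             rounds = 5, n_randomizations = 5, seed = 1))
  expect_lt(abs(r$mean_actual - 0.5), 0.15)
})

test_that("identical seeds give identical validation reports", {
  set.seed(9)
  x <- matrix(rnorm(40 * 4), 40, 4)
  ft <- feature_table(x, labels = rep(letters[1:4], each = 10))
  r1 <- suppressMessages(crossvalidate_randomized(ft, rounds = 3,
                                                  n_randomizations = 3,
                                                  seed = 5))
  r2 <- suppressMessages(crossvalidate_randomized(ft, rounds = 3,
                                                  n_randomizations = 3,
                                                  seed = 5))
  expect_identical(r1$actual_scores, r2$actual_scores)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("group scenarios drop and merge classes correctly", {
  set.seed(10)
  x <- matrix(rnorm(60 * 4), 60, 4)
  x[1:10, ] <- x[1:10, ] + 5
  labels <- rep(c("DAC", "HAC", "NGC-DA", "NGC-SA", "LAC", "SAC"), each = 10)
  ft <- feature_table(x, labels = labels)
  expect_error(lda_group_study(ft, drop_groups = "XYZ"), "unknown")

  # merging two coincident classes should not reduce separation of the rest
  r_full <- suppressMessages(lda_group_study(
    ft, rounds = 3, n_randomizations = 3, seed = 1))
  r_merge <- suppressMessages(lda_group_study(
    ft, merge_groups = list(NGC = c("NGC-DA", "NGC-SA")),
    rounds = 3, n_randomizations = 3, seed = 1))
  expect_gte(r_merge$mean_actual + 0.25, r_full$mean_actual)

  # dropping the one separated class reduces the achievable accuracy of the rest
  r_nodac <- suppressMessages(lda_group_study(
    ft, drop_groups = "DAC", rounds = 3, n_randomizations = 3, seed = 1))
  expect_lt(r_nodac$mean_actual, r_full$mean_actual + 0.05)
})
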