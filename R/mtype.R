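#' Feature table container
#'
#' Cells-by-features numeric matrix with optional class labels, the substrate
#' for feature power, PCA and LDA validation.
#'
#' @param values numeric matrix (cells x features) with unique column names;
#'   a data.frame with a `cell_id` column (e.g. from [morphometry_table()])
#'   is converted.
#' @param labels optional factor/character vector of class labels per cell.
#' @param cell_ids optional identifiers (default: rownames or `cell_id`
#'   column).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, labels = NULL, cell_ids = NULL) {
  if (is.data.frame(values)) {
    if ("cell_id" %in% names(values)) {
      if (is.null(cell_ids)) cell_ids <- values$cell_id
      values <- values[, setdiff(names(values), "cell_id"), drop = FALSE]
    }
    values <- as.matrix(values)
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  blank <- !nzchar(colnames(values))
  colnames(values)[blank] <- paste0("f", which(blank))
  if (anyDuplicated(colnames(values))) stop("feature names must be unique")
  if (is.null(cell_ids)) {
    cell_ids <- if (!is.null(rownames(values))) rownames(values) else
      paste0("cell", seq_len(nrow(values)))
  }
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    if (length(labels) != nrow(values)) stop("labels length mismatch")
  }
  structure(list(values = values, labels = labels,
                 cell_ids = as.character(cell_ids)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d cells x %d features", nrow(x$values),
              ncol(x$values)))
  if (!is.null(x$labels)) {
    cat(";", nlevels(x$labels), "classes:",
        paste(levels(x$labels), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

as_feature_table <- function(table, labels = NULL) {
  if (inherits(table, "feature_table")) {
    if (!is.null(labels)) table$labels <- as.factor(labels)
    return(table)
  }
  feature_table(table, labels = labels)
}

#' Drop features by name or index
#'
#' The raw battery carries two features with high coefficients of variation
#' (the two arbor tortuosity means) that are excluded before normalization by
#' default in the validation pipeline.
#'
#' @param table a [feature_table()].
#' @param drop character names or integer indices of features to remove.
#' @return The reduced `feature_table`.
#' @export
drop_features <- function(table,
                          drop = c("axon_tortuosity", "dend_tortuosity")) {
  table <- as_feature_table(table)
  keep <- if (is.numeric(drop)) setdiff(seq_len(ncol(table$values)), drop)
          else setdiff(colnames(table$values), drop)
  table$values <- table$values[, keep, drop = FALSE]
  table
}

#' Z-normalize a feature table
#'
#' Each feature column is centred on its mean and scaled to unit sample SD.
#' Constant columns cannot be scaled; they are dropped with a warning.
#'
#' @param table a [feature_table()] (or matrix/data.frame).
#' @return The normalized `feature_table` with attribute `dropped` naming any
#'   constant features removed.
#' @export
znormalize <- function(table) {
  table <- as_feature_table(table)
  if (nrow(table$values) < 2) stop("at least 2 cells required")
  sds <- apply(table$values, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(table$values)[const], collapse = ", "))
  }
  v <- scale(table$values[, !const, drop = FALSE])
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  table$values <- v
  attr(table, "dropped") <- colnames(table$values)[const]
  table
}

#' Flag outlier cells in a normalized feature table
#'
#' A cell is flagged when any of its feature z-scores exceeds `sd_limit` in
#' magnitude; the report lists the maximal |z| and the offending features per
#' flagged cell.
#'
#' @param table a z-normalized [feature_table()].
#' @param sd_limit flag threshold in SD units.
#' @return A data.frame with one row per flagged cell: `cell_id`, `max_z`,
#'   `features` (comma-separated offenders). Zero rows when nothing is
#'   flagged.
#' @export
flag_outliers <- function(table, sd_limit = 2) {
  table <- as_feature_table(table)
  z <- abs(table$values)
  flagged <- which(apply(z, 1, max) > sd_limit)
  out <- lapply(flagged, function(i) {
    off <- which(z[i, ] > sd_limit)
    data.frame(cell_id = table$cell_ids[i], max_z = max(z[i, ]),
               features = paste(colnames(z)[off], collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (length(out) == 0) {
    return(data.frame(cell_id = character(0), max_z = numeric(0),
                      features = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Feature power: per-feature class discrimination
#'
#' For each (z-scored) feature: `variance` is the pooled within-class
#' variance and `var_ratio` the between-class share of the total sum of
#' squares (the one-way ANOVA eta squared). Features are ranked by
#' `var_ratio` descending; high-ratio features are the most discriminative.
#' Classes with a single member cannot contribute a within-class variance and
#' are excluded from the pooling (with a message).
#'
#' @param table a [feature_table()] (z-normalized for the canonical usage).
#' @param labels class labels (default: the table's own).
#' @return A data.frame `feature`, `variance`, `var_ratio`, sorted by
#'   `var_ratio` descending.
#' @export
feature_power <- function(table, labels = NULL) {
  table <- as_feature_table(table, labels)
  labels <- table$labels
  if (is.null(labels) || nlevels(droplevels(labels)) < 2) {
    stop("at least 2 classes required")
  }
  labels <- droplevels(labels)
  sizes <- table(labels)
  if (any(sizes < 2)) {
    message("excluding single-member class(es) from within-class pooling: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  pool_ok <- labels %in% names(sizes)[sizes >= 2]
  v <- table$values
  res <- lapply(colnames(v), function(f) {
    x <- v[, f]
    grand <- mean(x)
    ssb <- sum(tapply(x, labels, function(g) length(g) * (mean(g) - grand)^2))
    sst <- sum((x - grand)^2)
    xp <- x[pool_ok]; lp <- droplevels(labels[pool_ok])
    ssw <- sum(tapply(xp, lp, function(g) sum((g - mean(g))^2)))
    pooled_var <- ssw / (length(xp) - nlevels(lp))
    data.frame(feature = f, variance = pooled_var,
               var_ratio = if (sst > 0) ssb / sst else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(-out$var_ratio), ]
}

#' Principal component analysis of a feature table
#'
#' Unsupervised dimensionality reduction on the (normalized) feature matrix;
#' components are orthonormal and ordered by explained variance, and the
#' explained-variance fractions sum to 1.
#'
#' @param table a [feature_table()], normally z-normalized first.
#' @return List of class `pca_result`: `components` (features x components,
#'   orthonormal columns), `explained_variance_fractions`, `projections`
#'   (cells x components), `sdev`.
#' @export
run_pca <- function(table) {
  table <- as_feature_table(table)
  if (nrow(table$values) < 2) stop("at least 2 cells required")
  p <- stats::prcomp(table$values, center = TRUE, scale. = FALSE)
  fr <- p$sdev^2 / sum(p$sdev^2)
  structure(list(components = p$rotation,
                 explained_variance_fractions = fr,
                 projections = p$x, sdev = p$sdev),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  fr <- x$explained_variance_fractions
  cat(sprintf("<pca_result> %d components; leading fractions: %s\n",
              length(fr),
              paste(sprintf("%.3f", utils::head(fr, 5)), collapse = ", ")))
  invisible(x)
}

# Ridge-regularized Fisher discriminant used when the within-class scatter is
# singular (more features than cells minus classes).
ridge_lda <- function(x, labels, lambda) {
  labels <- droplevels(as.factor(labels))
  k <- nlevels(labels)
  p <- ncol(x)
  grand <- colMeans(x)
  sw <- matrix(0, p, p)
  sb <- matrix(0, p, p)
  means <- matrix(0, k, p, dimnames = list(levels(labels), colnames(x)))
  for (g in levels(labels)) {
    xg <- x[labels == g, , drop = FALSE]
    mg <- colMeans(xg)
    means[g, ] <- mg
    cg <- sweep(xg, 2, mg)
    sw <- sw + crossprod(cg)
    sb <- sb + nrow(xg) * tcrossprod(mg - grand)
  }
  sw <- sw / (nrow(x) - k) + lambda * diag(p)
  e <- eigen(solve(sw, sb), symmetric = FALSE)
  w <- Re(e$vectors[, seq_len(min(k - 1, p)), drop = FALSE])
  list(weights = w, means = means, sw = sw, labels = levels(labels))
}

#' Linear discriminant analysis of labelled features
#'
#' Fisher LDA: projections maximizing the ratio of between-class to
#' within-class variance. When the within-class scatter is singular (more
#' features than cells minus classes) a ridge-regularized fit is used and
#' noted in the result.
#'
#' @param table a [feature_table()] with labels (or a matrix + `labels`).
#' @param labels class labels (default: the table's own); each class needs
#'   >= 2 members.
#' @param n_components number of discriminants to keep (default: classes-1).
#' @param regularize force the ridge-regularized path.
#' @param lambda ridge penalty for the regularized path.
#' @return List of class `lda_result`: `projections`, `class_means` (on the
#'   discriminant axes), `weight_vectors`, `regularized`, `model` (the
#'   underlying `MASS::lda` fit when unregularized).
#' @export
run_lda <- function(table, labels = NULL, n_components = NULL,
                    regularize = FALSE, lambda = 1e-3) {
  table <- as_feature_table(table, labels)
  labels <- droplevels(table$labels)
  if (is.null(labels)) stop("labels required")
  if (nlevels(labels) < 2) stop("at least 2 classes required")
  if (any(table(labels) < 2)) stop("each class needs at least 2 members")
  x <- table$values
  k <- nlevels(labels)
  if (is.null(n_components)) n_components <- k - 1
  singular <- ncol(x) > nrow(x) - k
  if (singular && !regularize) {
    message("within-class scatter is singular (features > cells - classes); ",
            "applying ridge regularization")
    regularize <- TRUE
  }
  if (!regularize) {
    fit <- MASS::lda(x, grouping = labels)
    w <- fit$scaling[, seq_len(min(n_components, ncol(fit$scaling))),
                     drop = FALSE]
    proj <- x %*% w
    cm <- fit$means %*% w
    structure(list(projections = proj, class_means = cm, weight_vectors = w,
                   regularized = FALSE, model = fit),
              class = "lda_result")
  } else {
    fit <- ridge_lda(x, labels, lambda)
    w <- fit$weights[, seq_len(min(n_components, ncol(fit$weights))),
                     drop = FALSE]
    structure(list(projections = x %*% w, class_means = fit$means %*% w,
                   weight_vectors = w, regularized = TRUE, model = fit),
              class = "lda_result")
  }
}

# stratified fold assignment: per class, cells are dealt round-robin into
# folds in a random order
stratified_folds <- function(labels, folds) {
  out <- integer(length(labels))
  for (g in levels(labels)) {
    ix <- which(labels == g)
    out[ix] <- sample(rep_len(seq_len(folds), length(ix)))
  }
  out
}

# one round of stratified k-fold CV; returns per-fold accuracy
cv_round <- function(x, labels, folds) {
  fold_of <- stratified_folds(labels, folds)
  vapply(seq_len(folds), function(f) {
    tr <- fold_of != f
    te <- !tr
    if (!any(te)) return(NA_real_)
    train_labels <- droplevels(labels[tr])
    # folds can strand a class with < 2 training members; fall back to the
    # ridge path which tolerates it
    fit <- try(MASS::lda(x[tr, , drop = FALSE], grouping = train_labels),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      rl <- ridge_lda(x[tr, , drop = FALSE], train_labels, 1e-3)
      proj_tr <- x[tr, , drop = FALSE] %*% rl$weights
      proj_te <- x[te, , drop = FALSE] %*% rl$weights
      cm <- rl$means %*% rl$weights
      pred <- rl$labels[apply(proj_te, 1, function(r) {
        which.min(colSums((t(cm) - r)^2))
      })]
    } else {
      pred <- as.character(stats::predict(fit, x[te, , drop = FALSE])$class)
    }
    mean(pred == as.character(labels[te]))
  }, numeric(1))
}

#' Cross-validated class separation with label randomization
#'
#' The overfitting control for the supervised classification: `rounds` rounds
#' of stratified `folds`-fold cross-validation of an LDA classifier on the
#' actual labels, repeated on `n_randomizations` label-shuffled replicates of
#' the same data. Two comparisons are reported. `t_statistic` / `p_value_pooled`
#' is the Welch two-sample t-test of the actual per-fold accuracies against
#' the pooled randomized ones; fold scores are not independent (they share
#' one label assignment), which makes this comparison anti-conservative as a
#' significance test, so it is reported for descriptive comparison. The
#' primary `p_value` is a calibrated randomization test: the actual mean CV
#' score is referred to the distribution of per-randomization mean scores via
#' a one-sample t statistic with `n_randomizations - 1` degrees of freedom
#' (one-sided, actual greater than randomized) -- under label-free data the
#' actual labeling is exchangeable with the shuffled ones, so this test holds
#' its nominal level. If the smallest class has fewer members than `folds`,
#' the fold count is shrunk to it (stratified fold shrinkage, with a
#' message).
#'
#' @param table a [feature_table()] with labels.
#' @param labels class labels (default: the table's own).
#' @param rounds,folds cross-validation design.
#' @param n_randomizations number of label-shuffled replicates.
#' @param seed integer seed.
#' @return A list of class `validation_report`: `actual_scores` (rounds x
#'   folds accuracies), `randomized_scores` (pooled), `t_statistic`,
#'   `p_value_pooled` (Welch on pooled fold scores), `t_calibrated`,
#'   `p_value` (calibrated randomization-level test), `mean_actual`,
#'   `mean_randomized`, `randomization_means`, `folds_used`.
#' @export
crossvalidate_randomized <- function(table, labels = NULL, rounds = 10,
                                     folds = 10, n_randomizations = 10,
                                     seed = 1) {
  table <- as_feature_table(table, labels)
  labels <- droplevels(table$labels)
  if (is.null(labels)) stop("labels required")
  if (nlevels(labels) < 2) stop("degenerate single-class input")
  x <- table$values
  min_class <- min(table(labels))
  folds_used <- folds
  if (min_class < folds) {
    folds_used <- max(2L, min_class)
    message("smallest class has ", min_class, " members; shrinking to ",
            folds_used, "-fold CV")
  }
  with_seed(seed, {
    actual <- unlist(lapply(seq_len(rounds), function(r) {
      cv_round(x, labels, folds_used)
    }))
    rand_runs <- lapply(seq_len(n_randomizations), function(j) {
      shuffled <- factor(sample(as.character(labels)), levels(labels))
      unlist(lapply(seq_len(rounds), function(r) {
        cv_round(x, shuffled, folds_used)
      }))
    })
    randomized <- unlist(rand_runs)
    tt <- stats::t.test(actual, randomized)
    m_act <- mean(actual, na.rm = TRUE)
    m_rand <- vapply(rand_runs, mean, numeric(1), na.rm = TRUE)
    s_rand <- stats::sd(m_rand)
    j <- length(m_rand)
    if (s_rand > 0) {
      t_cal <- (m_act - mean(m_rand)) / (s_rand * sqrt(1 + 1 / j))
      p_cal <- stats::pt(t_cal, df = j - 1, lower.tail = FALSE)
    } else {
      t_cal <- if (m_act > mean(m_rand)) Inf else 0
      p_cal <- if (m_act > mean(m_rand)) 0 else 1
    }
    structure(
      list(actual_scores = actual, randomized_scores = randomized,
           t_statistic = unname(tt$statistic), p_value_pooled = tt$p.value,
           t_calibrated = t_cal, p_value = p_cal,
           mean_actual = m_act, mean_randomized = mean(randomized, na.rm = TRUE),
           randomization_means = m_rand,
           folds_used = folds_used),
      class = "validation_report"
    )
  })
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> actual accuracy %.3f vs randomized %.3f (t = %.2f, p = %.3g)\n",
    x$mean_actual, x$mean_randomized, x$t_statistic, x$p_value))
  invisible(x)
}

#' Grouped LDA validation scenarios
#'
#' Runs the randomized cross-validation over class-grouping scenarios:
#' the full label set, the label set with groups dropped, and/or with groups
#' merged (e.g. dropping the descending-axon class, or merging the two
#' neurogliaform classes into one).
#'
#' @param table a [feature_table()] with labels.
#' @param labels class labels (default: the table's own).
#' @param drop_groups character vector of class labels to remove (cells of
#'   those classes are excluded). Unknown names are an error.
#' @param merge_groups named list: each element is a character vector of
#'   existing labels to merge, named by the merged label.
#' @param ... passed to [crossvalidate_randomized()].
#' @return A `validation_report` for the requested scenario.
#' @export
lda_group_study <- function(table, labels = NULL, drop_groups = NULL,
                            merge_groups = NULL, ...) {
  table <- as_feature_table(table, labels)
  labels <- as.character(table$labels)
  known <- unique(labels)
  if (!is.null(drop_groups)) {
    bad <- setdiff(drop_groups, known)
    if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
    keep <- !labels %in% drop_groups
    table$values <- table$values[keep, , drop = FALSE]
    table$cell_ids <- table$cell_ids[keep]
    labels <- labels[keep]
  }
  if (!is.null(merge_groups)) {
    for (new in names(merge_groups)) {
      bad <- setdiff(merge_groups[[new]], unique(labels))
      if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
      labels[labels %in% merge_groups[[new]]] <- new
    }
  }
  table$labels <- factor(labels)
  crossvalidate_randomized(table, ...)
}
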