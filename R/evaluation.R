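# Evaluation protocol: SMOTE class balancing, stratified k-fold
# cross-validation, five performance metrics, and the k-fold cross-validated
# paired t-test for comparing learners.

#' SMOTE class balancing
#'
#' Oversamples the minority class to the majority count by synthesizing
#' convex combinations of each minority sample and one of its k nearest
#' minority-class neighbors (Euclidean distance). Deterministic under the
#' seed; `k_neighbors` is reduced automatically when the minority class is
#' small.
#'
#' @param features Numeric matrix/data frame.
#' @param labels Factor/vector of `"healthy"` / `"jaundiced"`.
#' @param seed Integer seed.
#' @param k_neighbors Number of nearest neighbors considered (default 5).
#' @return List with balanced `features` (matrix), `labels`, and `synthetic`
#'   (logical marker for generated rows).
#' @export
smote_balance <- function(features, labels, seed = 1L, k_neighbors = 5L) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- as_label_factor(labels)
  counts <- table(y)
  if (any(counts == 0))
    return(list(features = x, labels = y, synthetic = rep(FALSE, nrow(x))))
  minority <- names(which.min(counts))
  deficit <- max(counts) - min(counts)
  if (deficit == 0)
    return(list(features = x, labels = y, synthetic = rep(FALSE, nrow(x))))
  min_idx <- which(y == minority)
  n_min <- length(min_idx)
  if (n_min < 2)
    stop("SMOTE requires at least 2 minority samples", call. = FALSE)
  k <- min(k_neighbors, n_min - 1L)
  xm <- x[min_idx, , drop = FALSE]
  dm <- as.matrix(stats::dist(xm))
  diag(dm) <- Inf
  nn <- t(apply(dm, 1, function(row) order(row)[seq_len(k)]))
  set.seed(seed)
  base_pick <- min_idx[((seq_len(deficit) - 1L) %% n_min) + 1L]
  synth <- matrix(0, deficit, ncol(x))
  for (j in seq_len(deficit)) {
    i_min <- match(base_pick[j], min_idx)
    neighbor <- nn[i_min, sample.int(k, 1L)]
    gap <- stats::runif(1)
    synth[j, ] <- xm[i_min, ] + gap * (xm[neighbor, ] - xm[i_min, ])
  }
  colnames(synth) <- colnames(x)
  list(features = rbind(x, synth),
       labels = as_label_factor(c(as.character(y), rep(minority, deficit))),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, deficit)))
}

#' Stratified k-fold split
#'
#' Partitions sample indices into k disjoint test folds with per-fold class
#' counts within one of proportional allocation.
#'
#' @param labels Factor/vector of class labels.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the shuffling.
#' @return List of k integer index vectors (the test sets).
#' @export
stratified_kfold_split <- function(labels, k = 5L, seed = 1L) {
  y <- factor(labels)
  if (any(table(y) < k))
    stop("every class must have at least k = ", k, " members", call. = FALSE)
  set.seed(seed)
  folds <- vector("list", k)
  totals <- integer(k)
  # larger classes first; each class's remainder goes to the currently
  # smallest folds so fold sizes stay within one of each other
  for (cl in names(sort(table(y), decreasing = TRUE))) {
    idx <- sample(which(y == cl))
    n_c <- length(idx)
    counts <- rep(n_c %/% k, k)
    extras <- n_c %% k
    if (extras > 0) {
      recipients <- order(totals)[seq_len(extras)]
      counts[recipients] <- counts[recipients] + 1L
    }
    pos <- 0L
    for (f in seq_len(k)) {
      if (counts[f] > 0) folds[[f]] <- c(folds[[f]], idx[pos + seq_len(counts[f])])
      pos <- pos + counts[f]
    }
    totals <- totals + counts
  }
  lapply(folds, sort)
}

#' Classification metrics for one fold
#'
#' Computes accuracy, macro-averaged precision and recall, their harmonic
#' mean as the F1 score, and the AUC (probability that a random jaundiced
#' sample scores above a random healthy one, ties counting one half).
#'
#' @param true_labels,predicted_labels Factors/vectors of
#'   `"healthy"` / `"jaundiced"`.
#' @param scores Numeric jaundiced-class probabilities.
#' @param fold_id Optional fold identifier stored in the result.
#' @return List of class `fold_metrics` with `accuracy`, `precision`,
#'   `recall`, `f1`, `auc` in `[0, 1]`.
#' @export
compute_metrics <- function(true_labels, predicted_labels, scores, fold_id = NA) {
  y <- as_label_factor(true_labels)
  p <- as_label_factor(predicted_labels)
  if (length(y) != length(p) || length(y) != length(scores))
    stop("inputs must have equal length", call. = FALSE)
  if (nlevels(droplevels(y)) < 2)
    stop("AUC undefined: only one class present in true labels", call. = FALSE)
  accuracy <- mean(y == p)
  per_class <- vapply(CLASS_LEVELS, function(cl) {
    tp <- sum(y == cl & p == cl)
    prec <- if (sum(p == cl) == 0) 0 else tp / sum(p == cl)
    rec <- tp / sum(y == cl)
    c(prec, rec)
  }, numeric(2))
  precision <- mean(per_class[1, ])
  recall <- mean(per_class[2, ])
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  r <- rank(scores)   # average ranks give ties weight 1/2
  n_j <- sum(y == "jaundiced"); n_h <- sum(y == "healthy")
  auc <- (sum(r[y == "jaundiced"]) - n_j * (n_j + 1) / 2) / (n_j * n_h)
  structure(list(fold_id = fold_id, accuracy = accuracy, precision = precision,
                 recall = recall, f1 = f1, auc = auc),
            class = "fold_metrics")
}

#' k-fold cross-validated paired t-test
#'
#' Compares two learners from their k paired per-fold scores. With
#' per-fold differences `p_i`, mean `p_bar`, and sample standard deviation
#' `s`, the statistic is `t = p_bar * sqrt(k) / s` on `k - 1` degrees of
#' freedom, with a two-sided p-value. Zero-variance differences give
#' `t = 0, p = 1` when the mean difference is zero, and are flagged
#' degenerate with `p = 0` otherwise.
#'
#' @param scores_a,scores_b Numeric vectors of k per-fold scores, paired by
#'   fold.
#' @return List of class `paired_test_result`: `t_statistic`, `df`,
#'   `p_value`, `per_fold_differences`, `mean_difference`, `degenerate`.
#' @examples
#' cv_paired_ttest(c(0.9, 0.8, 0.85, 0.9, 0.95), c(0.8, 0.6, 0.85, 0.8, 0.85))
#' @export
cv_paired_ttest <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must have equal length", call. = FALSE)
  k <- length(scores_a)
  if (k < 2) stop("at least 2 folds are required", call. = FALSE)
  d <- scores_a - scores_b
  d_bar <- mean(d)
  s <- stats::sd(d)
  degenerate <- s == 0
  if (degenerate) {
    t_stat <- if (d_bar == 0) 0 else sign(d_bar) * Inf
    p <- if (d_bar == 0) 1 else 0
  } else {
    t_stat <- d_bar * sqrt(k) / s
    p <- 2 * stats::pt(-abs(t_stat), df = k - 1)
  }
  structure(list(t_statistic = t_stat, df = k - 1L, p_value = p,
                 per_fold_differences = d, mean_difference = d_bar,
                 degenerate = degenerate),
            class = "paired_test_result")
}

METRIC_NAMES <- c("accuracy", "precision", "recall", "f1", "auc")

run_single_cv <- function(features, labels, config, folds, seed,
                          smote = c("within_fold", "pre_cv", "none")) {
  smote <- match.arg(smote)
  x <- as.matrix(features)
  y <- as_label_factor(labels)
  if (smote == "pre_cv") {
    bal <- smote_balance(x, y, seed = derive_seed(seed, 999L))
    # synthetic rows join every training set but are never tested
    x_extra <- bal$features[bal$synthetic, , drop = FALSE]
    y_extra <- bal$labels[bal$synthetic]
  }
  res <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_x <- x[-test_idx, , drop = FALSE]
    train_y <- y[-test_idx]
    if (smote == "within_fold") {
      bal <- smote_balance(train_x, train_y, seed = derive_seed(seed, f))
      train_x <- bal$features; train_y <- bal$labels
    } else if (smote == "pre_cv") {
      train_x <- rbind(train_x, x_extra)
      train_y <- as_label_factor(c(as.character(train_y), as.character(y_extra)))
    }
    cfg <- config
    cfg$seed <- derive_seed(config$seed, f)
    model <- train_model(cfg, train_x, train_y)
    scores <- predict_proba(model, x[test_idx, , drop = FALSE])[, "jaundiced"]
    pred <- factor(ifelse(scores >= 0.5, "jaundiced", "healthy"), levels = CLASS_LEVELS)
    res[[f]] <- compute_metrics(y[test_idx], pred, scores, fold_id = f)
  }
  do.call(rbind, lapply(res, function(m)
    data.frame(fold = m$fold_id, accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1, auc = m$auc)))
}

#' Run the full model-comparison experiment
#'
#' For every (feature set, model) combination: stratified k-fold
#' cross-validation with SMOTE applied to the training portion of each fold
#' (so synthetic samples never leak into a test fold), per-fold metrics on
#' the untouched test fold, and all pairwise k-fold cross-validated paired
#' t-tests between combinations for each metric.
#'
#' @param features_by_set Named list of feature data frames (one per feature
#'   set, e.g. from [cohort_features()]), each with a `label` column and
#'   feature columns; rows must describe the same subjects in the same
#'   order.
#' @param model_configs Named list of [model_config()] objects; defaults to
#'   the four traditional models.
#' @param k Number of folds.
#' @param seed Master seed for fold assignment, SMOTE, and training.
#' @param alpha Significance level recorded in the report.
#' @param smote `"within_fold"` (default), `"pre_cv"` (oversample once
#'   before splitting, for comparison), or `"none"`.
#' @return An object of class `comparison_report`: `per_fold` (data frame of
#'   per-fold metrics), `means` (per-combination metric means), `pairwise`
#'   (paired-test table with columns `feature_set_a`, `model_a`,
#'   `feature_set_b`, `model_b`, `metric`, `t`, `df`, `p`), `alpha`, `k`.
#' @export
run_experiment <- function(features_by_set, model_configs = default_model_configs(seed),
                           k = 5L, seed = 1L, alpha = 0.05,
                           smote = c("within_fold", "pre_cv", "none")) {
  smote <- match.arg(smote)
  stopifnot(is.list(features_by_set), length(features_by_set) >= 1,
            !is.null(names(features_by_set)))
  labels <- as_label_factor(features_by_set[[1]]$label)
  for (nm in names(features_by_set)) {
    if (!identical(as.character(features_by_set[[nm]]$label), as.character(labels)))
      stop("feature sets disagree on subject labels", call. = FALSE)
  }
  folds <- stratified_kfold_split(labels, k = k, seed = seed)
  per_fold <- NULL
  for (fs in names(features_by_set)) {
    df <- features_by_set[[fs]]
    x <- df[, setdiff(colnames(df), c("subject_id", "label")), drop = FALSE]
    for (mk in names(model_configs)) {
      res <- tryCatch(
        run_single_cv(x, labels, model_configs[[mk]], folds,
                      seed = derive_seed(seed, match(fs, names(features_by_set)) * 100L +
                                           match(mk, names(model_configs))),
                      smote = smote),
        error = function(e) stop("evaluation failed for feature_set=", fs,
                                 ", model=", mk, ": ", conditionMessage(e),
                                 call. = FALSE))
      per_fold <- rbind(per_fold,
                        cbind(data.frame(feature_set = fs, model = mk), res))
    }
  }
  means <- stats::aggregate(per_fold[, METRIC_NAMES],
                            by = per_fold[, c("feature_set", "model")], FUN = mean)
  combos <- unique(per_fold[, c("feature_set", "model")])
  pairwise <- NULL
  if (nrow(combos) >= 2) {
    for (i in seq_len(nrow(combos) - 1)) for (j in (i + 1):nrow(combos)) {
      a <- per_fold[per_fold$feature_set == combos$feature_set[i] &
                      per_fold$model == combos$model[i], ]
      b <- per_fold[per_fold$feature_set == combos$feature_set[j] &
                      per_fold$model == combos$model[j], ]
      a <- a[order(a$fold), ]; b <- b[order(b$fold), ]
      for (m in METRIC_NAMES) {
        tt <- cv_paired_ttest(a[[m]], b[[m]])
        pairwise <- rbind(pairwise, data.frame(
          feature_set_a = combos$feature_set[i], model_a = combos$model[i],
          feature_set_b = combos$feature_set[j], model_b = combos$model[j],
          metric = m, t = tt$t_statistic, df = tt$df, p = tt$p_value))
      }
    }
  }
  structure(list(per_fold = per_fold, means = means, pairwise = pairwise,
                 alpha = alpha, k = as.integer(k), seed = as.integer(seed),
                 smote = smote),
            class = "comparison_report")
}

#' Run the experiment directly from scenes
#'
#' Featurizes a scene cohort for each requested feature set, then calls
#' [run_experiment()].
#'
#' @param scenes List of `jaundice_scene` objects.
#' @param feature_sets Character vector among `"skin"`, `"eye"`, `"fusion"`.
#' @inheritParams run_experiment
#' @return A `comparison_report`.
#' @export
evaluate_scenes <- function(scenes, feature_sets = c("skin", "eye", "fusion"),
                            model_configs = default_model_configs(seed),
                            k = 5L, seed = 1L, alpha = 0.05,
                            smote = "within_fold") {
  features_by_set <- stats::setNames(
    lapply(feature_sets, function(fs) cohort_features(scenes, fs)), feature_sets)
  run_experiment(features_by_set, model_configs, k = k, seed = seed,
                 alpha = alpha, smote = smote)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", x$k, "-fold CV, SMOTE: ", x$smote,
      ", alpha = ", x$alpha, "\n\nMean metrics over folds:\n", sep = "")
  print(format(x$means, digits = 3), row.names = FALSE)
  if (!is.null(x$pairwise)) {
    sig <- x$pairwise[x$pairwise$p < x$alpha, ]
    cat("\nPairwise tests: ", nrow(x$pairwise), " (",
        nrow(sig), " significant at alpha)\n", sep = "")
  }
  invisible(x)
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat("k-fold CV paired t-test: t =", format(x$t_statistic, digits = 4),
      "df =", x$df, "p =", format(x$p_value, digits = 4),
      if (x$degenerate) "(degenerate: zero-variance differences)" else "", "\n")
  invisible(x)
}
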