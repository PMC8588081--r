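# SMOTE, stratified folds, metrics, and the CV paired t-test.

test_that("SMOTE equalizes class counts with convex-combination samples", {
  set.seed(61)
  x <- rbind(matrix(rnorm(44 * 3, 10), ncol = 3), matrix(rnorm(24 * 3), ncol = 3))
  y <- c(rep("healthy", 44), rep("jaundiced", 24))
  bal <- smote_balance(x, y, seed = 1)
  expect_equal(as.integer(table(bal$labels)), c(44L, 44L))
  expect_equal(sum(bal$synthetic), 20)
  expect_identical(bal$features[1:68, ], unname(x))

  # minority on a segment -> synthetic points stay on the segment
  seg <- rbind(matrix(rnorm(30), 10, 3), t(sapply(seq(0, 1, length.out = 4),
                                                  function(t) c(t, 2 * t, 3 * t))))
  yl <- c(rep("healthy", 10), rep("jaundiced", 4))
  bs <- smote_balance(seg, yl, seed = 2)
  synth <- bs$features[bs$synthetic, , drop = FALSE]
  expect_equal(synth[, 2] / pmax(synth[, 1], 1e-12), rep(2, nrow(synth)),
               tolerance = 1e-8)
  expect_true(all(synth[, 1] >= 0 & synth[, 1] <= 1))
})

test_that("SMOTE is deterministic, identity on balance, and guards tiny minorities", {
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c("healthy", "jaundiced"), 10)
  bal <- smote_balance(x, y, seed = 3)
  expect_identical(bal$features, x)
  expect_false(any(bal$synthetic))

  x2 <- matrix(rnorm(20), 10, 2)
  expect_error(smote_balance(x2, c(rep("healthy", 9), "jaundiced")),
               "at least 2 minority")
  b1 <- smote_balance(x2, c(rep("healthy", 7), rep("jaundiced", 3)), seed = 9)
  b2 <- smote_balance(x2, c(rep("healthy", 7), rep("jaundiced", 3)), seed = 9)
  expect_identical(b1$features, b2$features)
})

test_that("stratified folds partition indices with near-proportional classes", {
  y <- c(rep("healthy", 20), rep("jaundiced", 20))
  folds <- stratified_kfold_split(y, k = 5, seed = 1)
  expect_equal(sort(unlist(folds)), 1:40)
  for (f in folds) expect_equal(as.integer(table(y[f])), c(4L, 4L))

  y2 <- c(rep("healthy", 44), rep("jaundiced", 24))
  folds2 <- stratified_kfold_split(y2, k = 5, seed = 2)
  expect_equal(sort(unlist(folds2)), 1:68)
  sizes <- lengths(folds2)
  expect_true(all(sizes %in% c(13, 14)))
  jcounts <- vapply(folds2, function(f) sum(y2[f] == "jaundiced"), 0L)
  expect_true(all(jcounts %in% c(4L, 5L)))

  expect_error(stratified_kfold_split(c(rep("healthy", 10), rep("jaundiced", 3)), k = 5),
               "at least k")
})

test_that("metrics match brute-force confusion-table and pairwise-AUC counting", {
  m <- compute_metrics(c("jaundiced", "jaundiced", "healthy", "healthy"),
                       c("jaundiced", "healthy", "healthy", "healthy"),
                       c(0.9, 0.4, 0.3, 0.2))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 5 / 6)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 2 * (5 / 6) * 0.75 / (5 / 6 + 0.75))
  expect_equal(m$auc, 1)

  perfect <- compute_metrics(c("jaundiced", "healthy"), c("jaundiced", "healthy"),
                             c(1, 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1", "auc")]),
               rep(1, 5), ignore_attr = TRUE)

  ties <- compute_metrics(rep(c("jaundiced", "healthy"), 3), rep("healthy", 6),
                          rep(0.4, 6))
  expect_equal(ties$auc, 0.5)

  expect_error(compute_metrics(rep("healthy", 4), rep("healthy", 4), runif(4)),
               "one class")
})

test_that("tie-aware AUC equals brute-force pair counting on random data", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    y <- sample(c("healthy", "jaundiced"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # coarse grid forces ties
    m <- compute_metrics(y, sample(c("healthy", "jaundiced"), n, TRUE), s)
    pairs <- expand.grid(j = which(y == "jaundiced"), h = which(y == "healthy"))
    brute <- mean(ifelse(s[pairs$j] > s[pairs$h], 1,
                         ifelse(s[pairs$j] == s[pairs$h], 0.5, 0)))
    expect_equal(m$auc, brute)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ext <- as.numeric(pROC::auc(pROC::roc(y, s, levels = c("healthy", "jaundiced"),
                                            direction = "<", quiet = TRUE)))
      expect_equal(m$auc, ext)
    }
  }
})

test_that("cv paired t-test matches hand arithmetic and the t.test oracle", {
  a <- c(0.9, 0.8, 0.85, 0.9, 0.95)
  b <- a - c(0.1, 0.2, 0.0, 0.1, 0.1)
  res <- cv_paired_ttest(a, b)
  expect_equal(res$t_statistic, 0.1 * sqrt(5) / sqrt(0.005), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$t_statistic, 3.162, tolerance = 1e-3)

  set.seed(72)
  for (i in 1:200) {
    x <- runif(5); y <- runif(5)
    mine <- cv_paired_ttest(x, y)
    oracle <- stats::t.test(x - y)
    expect_equal(mine$t_statistic, unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, oracle$p.value, tolerance = 1e-12)
  }
})

test_that("cv paired t-test is antisymmetric and handles degenerate input", {
  a <- c(0.8, 0.9, 0.7, 0.85, 0.8); b <- c(0.6, 0.95, 0.75, 0.7, 0.8)
  ab <- cv_paired_ttest(a, b); ba <- cv_paired_ttest(b, a)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  expect_equal(ab$p_value, ba$p_value)

  same <- cv_paired_ttest(a, a)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  shifted <- cv_paired_ttest(a + 0.1, a)
  expect_equal(shifted$p_value, 0)
  expect_true(shifted$degenerate)
  expect_error(cv_paired_ttest(a, a[1:3]), "equal length")
})

test_that("the experiment report is internally consistent and leak-free", {
  feats <- fixture_separable_features()
  configs <- list(dt = model_config("dt", seed = 2), rf = model_config("rf", seed = 3))
  rep <- run_experiment(list(fusion = feats), configs, k = 5, seed = 31)
  # means equal recomputed per-fold averages
  for (i in seq_len(nrow(rep$means))) {
    sel <- rep$per_fold$model == rep$means$model[i] &
      rep$per_fold$feature_set == rep$means$feature_set[i]
    expect_equal(rep$means$auc[i], mean(rep$per_fold$auc[sel]))
    expect_equal(rep$means$f1[i], mean(rep$per_fold$f1[sel]))
  }
  # folds partition the cohort
  folds <- stratified_kfold_split(feats$label, k = 5, seed = 31)
  expect_equal(sort(unlist(folds)), seq_len(nrow(feats)))
  expect_equal(anyDuplicated(unlist(folds)), 0)
  # pairwise table covers each metric once per model pair
  expect_equal(nrow(rep$pairwise), 5)
  expect_true(all(rep$pairwise$df == 4))
})

test_that("separable scene features give near-perfect discrimination", {
  feats <- fixture_separable_features()
  rep <- run_experiment(list(fusion = feats),
                        list(svm = model_config("svm", seed = 7),
                             rf = model_config("rf", seed = 8)),
                        k = 5, seed = 32)
  expect_gte(min(rep$means$auc), 0.9)
})
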