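# Traditional classifiers with the study's hyperparameter settings.
#
# Four models are supported on tabular color features:
#   mlp  two hidden layers of 200 rectified-linear units, dropout 0.5,
#        softmax output, cross-entropy loss, Adam, 50 epochs, batch 32
#        (implemented in-package; see mlp.R)
#   svm  radial-basis kernel, C = 1000, gamma = 0.7 (e1071 backend)
#   dt   CART, gini criterion, unlimited depth, min split 2 (rpart backend)
#   rf   random forest, 100 trees, gini (randomForest backend)
# Features are standardized with training-set statistics before svm and mlp
# (an RBF kernel with gamma 0.7 on raw 0-255 scales would degenerate);
# dt and rf consume raw features.

#' Model configuration
#'
#' Returns the default hyperparameters of one of the supported models,
#' optionally overridden. Defaults follow the study configuration for the
#' four traditional models; the `deep` configuration drives the small
#' transfer-learning-style branch (see [train_deep_model()]).
#'
#' @param model_kind One of `"mlp"`, `"svm"`, `"dt"`, `"rf"`, `"deep"`.
#' @param seed Integer seed making training deterministic.
#' @param ... Named hyperparameter overrides.
#' @return An object of class `model_config`.
#' @export
model_config <- function(model_kind = c("mlp", "svm", "dt", "rf", "deep"),
                         seed = 1L, ...) {
  model_kind <- match.arg(model_kind)
  hp <- switch(model_kind,
    mlp = list(hidden = c(200L, 200L), dropout = 0.5, epochs = 50L,
               batch_size = 32L, learning_rate = 1e-3),
    svm = list(kernel = "radial", cost = 1000, gamma = 0.7),
    dt = list(criterion = "gini", max_depth = 30L, min_split = 2L,
              min_bucket = 1L, cp = 0),
    rf = list(n_trees = 100L, criterion = "gini"),
    deep = list(n_filters = 64L, stride = 4L, head = c(128L, 64L),
                dropout = 0.5, epochs = 5L, batch_size = 16L,
                learning_rate = 1e-3, input_size = c(64L, 64L))
  )
  override <- list(...)
  bad <- setdiff(names(override), names(hp))
  if (length(bad)) stop("unknown hyperparameters: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  hp[names(override)] <- override
  structure(list(model_kind = model_kind, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "model_config")
}

prepare_xy <- function(features, labels) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- as_label_factor(labels)
  if (any(is.na(y))) stop("labels must be 'healthy' or 'jaundiced'", call. = FALSE)
  if (nrow(x) != length(y)) stop("features and labels length mismatch", call. = FALSE)
  if (any(table(y) < 2))
    stop("at least 2 samples per class are required for training", call. = FALSE)
  list(x = x, y = y)
}

standardizer <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

apply_standardizer <- function(x, st) {
  sweep(sweep(x, 2, st$center), 2, st$scale, "/")
}

#' Train a classifier
#'
#' Fits the configured model; training is deterministic under the
#' configuration seed.
#'
#' @param config A [model_config()] for `"mlp"`, `"svm"`, `"dt"`, or `"rf"`.
#' @param features Numeric matrix or data frame of feature columns.
#' @param labels Vector/factor of `"healthy"` / `"jaundiced"`, at least two
#'   samples of each.
#' @return An object of class `jaundice_model` exposing [predict_proba()].
#' @export
train_model <- function(config, features, labels) {
  stopifnot(inherits(config, "model_config"))
  if (config$model_kind == "deep")
    stop("use train_deep_model() for the deep branch", call. = FALSE)
  d <- prepare_xy(features, labels)
  hp <- config$hyperparameters
  set.seed(config$seed)
  st <- NULL
  fit <- switch(config$model_kind,
    svm = {
      st <- standardizer(d$x)
      xs <- apply_standardizer(d$x, st)
      m <- e1071::svm(x = xs, y = d$y, kernel = hp$kernel, cost = hp$cost,
                      gamma = hp$gamma, scale = FALSE)
      dv <- attr(stats::predict(m, xs, decision.values = TRUE), "decision.values")[, 1]
      # orient the decision value so positive means jaundiced
      flip <- mean(dv[d$y == "jaundiced"]) < mean(dv[d$y == "healthy"])
      list(svm = m, flip = flip)
    },
    dt = {
      df <- data.frame(.label = d$y, d$x, check.names = FALSE)
      rpart::rpart(.label ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(minsplit = hp$min_split,
                                                  minbucket = hp$min_bucket,
                                                  cp = hp$cp, xval = 0,
                                                  maxdepth = hp$max_depth))
    },
    rf = randomForest::randomForest(x = d$x, y = d$y, ntree = hp$n_trees),
    mlp = {
      st <- standardizer(d$x)
      mlp_fit(apply_standardizer(d$x, st), d$y, hidden = hp$hidden,
              dropout = hp$dropout, epochs = hp$epochs,
              batch_size = hp$batch_size, lr = hp$learning_rate,
              seed = config$seed)
    }
  )
  structure(list(model_kind = config$model_kind, fit = fit, standardizer = st,
                 feature_names = colnames(d$x), config = config),
            class = "jaundice_model")
}

#' Class probabilities of a trained model
#'
#' @param model A `jaundice_model` from [train_model()].
#' @param features Feature matrix/data frame with the training columns.
#' @return Numeric matrix, one row per sample, columns `healthy` and
#'   `jaundiced`, each row summing to 1. The `jaundiced` column is the score
#'   used for AUC.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "jaundice_model"))
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (ncol(x) != length(model$feature_names))
    stop("feature dimension mismatch: expected ", length(model$feature_names),
         " columns", call. = FALSE)
  if (!is.null(colnames(x)) && !identical(colnames(x), model$feature_names))
    x <- x[, model$feature_names, drop = FALSE]
  if (!is.null(model$standardizer)) x <- apply_standardizer(x, model$standardizer)
  p_j <- switch(model$model_kind,
    svm = {
      dv <- attr(stats::predict(model$fit$svm, x, decision.values = TRUE),
                 "decision.values")[, 1]
      if (model$fit$flip) dv <- -dv
      1 / (1 + exp(-dv))   # fixed logistic link: monotone in the signed margin
    },
    dt = {
      df <- as.data.frame(x)
      colnames(df) <- model$feature_names
      stats::predict(model$fit, df, type = "prob")[, "jaundiced"]
    },
    rf = stats::predict(model$fit, x, type = "prob")[, "jaundiced"],
    mlp = mlp_predict(model$fit, x)[, 2]
  )
  out <- cbind(healthy = 1 - p_j, jaundiced = p_j)
  rownames(out) <- rownames(x)
  out
}

#' Predicted class labels
#'
#' @inheritParams predict_proba
#' @param threshold Probability cutoff on the jaundiced score.
#' @return Factor of predicted labels.
#' @export
predict_label <- function(model, features, threshold = 0.5) {
  p <- predict_proba(model, features)[, "jaundiced"]
  factor(ifelse(p >= threshold, "jaundiced", "healthy"), levels = CLASS_LEVELS)
}

#' @export
print.jaundice_model <- function(x, ...) {
  cat("<jaundice_model>", x$model_kind, "on", length(x$feature_names),
      "features\n")
  invisible(x)
}

#' Default model set
#'
#' Configurations of the four traditional models, seeded from one master
#' seed.
#'
#' @param seed Master seed.
#' @return Named list of [model_config()] objects.
#' @export
default_model_configs <- function(seed = 1L) {
  kinds <- c("mlp", "svm", "dt", "rf")
  stats::setNames(lapply(seq_along(kinds), function(i)
    model_config(kinds[i], seed = derive_seed(seed, i))), kinds)
}
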