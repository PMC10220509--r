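new_divergence_model <- function(architecture, task, fit, config, m,
                                 feature_names, output_names = NULL,
                                 seed = NULL) {
  structure(list(architecture = architecture, task = task, fit = fit,
                 config = config, m = m, feature_names = feature_names,
                 output_names = output_names, seed = seed),
            class = "divergence_model")
}

#' @export
print.divergence_model <- function(x, ...) {
  cat(sprintf("Divergence model: %s (%s), m = %d conditions\n",
              toupper(x$architecture), x$task, x$m))
  invisible(x)
}

optimum_names <- function(m) {
  as.vector(vapply(seq_len(m), function(k)
    paste0(c("theta1", "theta2"), "_c", k), character(2)))
}

#' Random forest configuration
#'
#' Breiman-style forest: 500 unpruned trees, each grown on a bootstrap
#' resample of the full training set, choosing the best of `mtry`
#' randomly selected features at every split.  Node impurity is the Gini
#' index with minimum node size 10 for classification, and response
#' variance with minimum node size 5 for regression.  `mtry` defaults to
#' `floor(sqrt(p))` for classification and `max(floor(p / 3), 1)` for
#' regression.
#'
#' @param num_trees Number of trees.
#' @param mtry Features tried per split; `NULL` for the task default.
#' @param min_node_size Minimum node size; `NULL` for the task default
#'   (10 classification / 5 regression).
#' @return An object of class `"rf_config"`.
#' @export
rf_config <- function(num_trees = 500L, mtry = NULL, min_node_size = NULL) {
  stopifnot(num_trees >= 1L)
  structure(list(num_trees = as.integer(num_trees), mtry = mtry,
                 min_node_size = min_node_size),
            class = "rf_config")
}

#' Train the random forest
#'
#' Fits the forest of [rf_config()] via \pkg{ranger}.  Classification uses
#' probability trees; the predicted class is the one with the larger mean
#' estimated probability across trees (exact ties resolve to
#' `"conserved"`).  Regression fits one independent forest per output, so
#' `2m` forests predict the `2m` expression optima.
#'
#' @inheritParams train_nn
#' @param config An [rf_config()].
#' @return A `"divergence_model"` object.
#' @export
train_rf <- function(data, task = c("classification", "regression"),
                     config = rf_config(), seed = NULL) {
  task <- match.arg(task)
  stopifnot(inherits(data, "ortholog_data"))
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(data$features)
  if (task == "classification") {
    mtry <- if (is.null(config$mtry)) max(floor(sqrt(p)), 1L) else config$mtry
    node <- if (is.null(config$min_node_size)) 10L else config$min_node_size
    fit <- ranger::ranger(
      x = data$features, y = data$labels,
      num.trees = config$num_trees, mtry = mtry, min.node.size = node,
      probability = TRUE, num.threads = 1L,
      seed = sample.int(.Machine$integer.max, 1L))
  } else {
    mtry <- if (is.null(config$mtry)) max(floor(p / 3), 1L) else config$mtry
    node <- if (is.null(config$min_node_size)) 5L else config$min_node_size
    Y <- response_matrix(data, task)
    fit <- lapply(seq_len(ncol(Y)), function(k)
      ranger::ranger(x = data$features, y = Y[, k],
                     num.trees = config$num_trees, mtry = mtry,
                     min.node.size = node, num.threads = 1L,
                     seed = sample.int(.Machine$integer.max, 1L)))
    names(fit) <- colnames(Y)
  }
  new_divergence_model("rf", task, fit, config, data$m,
                       colnames(data$features),
                       output_names = if (task == "classification")
                         class_levels else optimum_names(data$m),
                       seed = seed)
}

#' Support vector machine configuration
#'
#' Radial-basis-function kernel `K(x, x') = exp(-gamma * ||x - x'||^2)`
#' with box constraint `0 <= mu_i <= C` on the dual coefficients.
#' Classification predicts by the sign of the kernel expansion;
#' regression is epsilon-insensitive with one machine per output.
#'
#' @param gamma RBF kernel width.
#' @param cost Box constraint `C` (> 0).
#' @param epsilon Unpenalized-residual margin for regression.
#' @return An object of class `"svm_config"`.
#' @export
svm_config <- function(gamma = 0.1, cost = 1, epsilon = 0.1) {
  stopifnot(gamma > 0, cost > 0, epsilon >= 0)
  structure(list(gamma = gamma, cost = cost, epsilon = epsilon),
            class = "svm_config")
}

#' Candidate grids for SVM tuning
#'
#' `svm_gamma_grid()` gives the 11 kernel widths chosen uniformly on a
#' logarithmic scale over `[0.001, 5]`; `svm_cost_grid()` gives `n` box
#' constraints log-uniform over `[0.01, 100]`.
#'
#' @param n Number of grid points.
#' @return Numeric vector of candidate values.
#' @export
svm_gamma_grid <- function(n = 11L) {
  10^seq(log10(0.001), log10(5), length.out = n)
}

#' @rdname svm_gamma_grid
#' @export
svm_cost_grid <- function(n = 10L) {
  10^seq(log10(0.01), log10(100), length.out = n)
}

#' Train the support vector machine
#'
#' Fits the RBF-kernel machine of [svm_config()] via \pkg{e1071} (libsvm):
#' C-classification with labels mapped to -1/+1, or epsilon-regression
#' with one machine per output.  Features are used unscaled (all inputs
#' are on the common log-expression scale).
#'
#' @inheritParams train_nn
#' @param config An [svm_config()].
#' @return A `"divergence_model"` object.  For classification the signed
#'   decision value is oriented so larger values mean more "diverged".
#' @export
train_svm <- function(data, task = c("classification", "regression"),
                      config = svm_config(), seed = NULL) {
  task <- match.arg(task)
  stopifnot(inherits(data, "ortholog_data"))
  if (!is.null(seed)) set.seed(seed)
  if (task == "classification") {
    fit <- e1071::svm(x = data$features, y = data$labels,
                      type = "C-classification", kernel = "radial",
                      gamma = config$gamma, cost = config$cost,
                      scale = FALSE)
  } else {
    Y <- response_matrix(data, task)
    fit <- lapply(seq_len(ncol(Y)), function(k)
      e1071::svm(x = data$features, y = Y[, k], type = "eps-regression",
                 kernel = "radial", gamma = config$gamma,
                 cost = config$cost, epsilon = config$epsilon,
                 scale = FALSE))
    names(fit) <- colnames(Y)
  }
  new_divergence_model("svm", task, fit, config, data$m,
                       colnames(data$features),
                       output_names = if (task == "classification")
                         class_levels else optimum_names(data$m),
                       seed = seed)
}

#' Tune the SVM kernel width and box constraint
#'
#' Grid search over `gamma_grid` x `cost_grid` with class-balanced k-fold
#' cross-validation, minimizing misclassification error (classification)
#' or mean squared error (regression).  Because kernel training cost grows
#' superlinearly in the sample size, a class-balanced row subsample can be
#' used for the search; the returned model is refit on the full data.
#'
#' @inheritParams cv_nn
#' @param gamma_grid,cost_grid Candidate kernel widths and box
#'   constraints.
#' @param n_subsample Optional number of rows used during the search.
#' @param config Base [svm_config()] supplying `epsilon`.
#' @return A list with `config` (best), `model` (refit on all data), `cv`
#'   (grid with mean validation losses), and `best_loss`.
#' @export
tune_svm <- function(data, task = c("classification", "regression"),
                     gamma_grid = svm_gamma_grid(),
                     cost_grid = svm_cost_grid(),
                     config = svm_config(), folds = 5L,
                     n_subsample = NULL, seed = NULL) {
  task <- match.arg(task)
  if (length(gamma_grid) == 0 || length(cost_grid) == 0)
    stop("empty hyperparameter grid")
  if (!is.null(seed)) set.seed(seed)
  cv_data <- data
  if (!is.null(n_subsample) && n_subsample < nrow(data$features)) {
    fold <- balanced_folds(data$labels,
                           floor(nrow(data$features) / n_subsample))
    cv_data <- subset_data(data, fold == 1L)
  }
  fold <- balanced_folds(cv_data$labels, folds)
  grid <- expand.grid(gamma = gamma_grid, cost = cost_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$loss <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- svm_config(grid$gamma[i], grid$cost[i], config$epsilon)
    mean(vapply(seq_len(folds), function(f) {
      train <- subset_data(cv_data, fold != f)
      valid <- subset_data(cv_data, fold == f)
      model <- train_svm(train, task, cfg)
      if (task == "classification") {
        pred <- predict_labels(model, valid$features)
        mean(pred$label != valid$labels)
      } else {
        mean((predict_optima(model, valid$features) -
                response_matrix(valid, task))^2)
      }
    }, numeric(1)))
  }, numeric(1))
  best <- which.min(grid$loss)
  best_config <- svm_config(grid$gamma[best], grid$cost[best],
                            config$epsilon)
  model <- train_svm(data, task, best_config)
  list(config = best_config, model = model, cv = grid,
       best_loss = grid$loss[best])
}

coerce_features <- function(model, x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != 2 * model$m)
    stop("feature matrix has ", ncol(x), " columns; expected ", 2 * model$m)
  colnames(x) <- model$feature_names
  x
}

#' Predict class labels and divergence scores
#'
#' The score is the estimated probability of the `"diverged"` class for
#' the NN and RF, and the signed distance to the separating hyperplane
#' (oriented so larger means more diverged) for the SVM.  An exact tie
#' (probability 0.5, or decision value 0) resolves to `"conserved"`, the
#' null-like class.
#'
#' @param model A classification `"divergence_model"`.
#' @param x Feature matrix (or single feature vector) with `2m`
#'   interleaved columns `e1_c1, e2_c1, ...`.
#' @return A `data.frame` with columns `label` (factor) and `score`.
#' @export
predict_labels <- function(model, x) {
  stopifnot(inherits(model, "divergence_model"))
  if (model$task != "classification")
    stop("predict_labels() requires a classification model")
  x <- coerce_features(model, x)
  score <- switch(model$architecture,
    nn = nn_forward(model, x)[, "diverged"],
    rf = predict(model$fit, data = x,
                 num.threads = 1L)$predictions[, "diverged"],
    svm = {
      pred <- predict(model$fit, newdata = x, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      # libsvm's decision value is positive for the first factor level;
      # orient so positive means "diverged"
      if (grepl("^conserved", colnames(dv)[1])) -dv[, 1] else dv[, 1]
    })
  threshold <- if (model$architecture == "svm") 0 else 0.5
  label <- factor(ifelse(score > threshold, "diverged", "conserved"),
                  levels = class_levels)
  data.frame(label = label, score = as.numeric(score))
}

#' Predict per-condition expression optima
#'
#' @param model A regression `"divergence_model"`.
#' @inheritParams predict_labels
#' @return A numeric matrix with `2m` columns ordered
#'   `theta1_c1, theta2_c1, ..., theta1_cm, theta2_cm`.
#' @export
predict_optima <- function(model, x) {
  stopifnot(inherits(model, "divergence_model"))
  if (model$task != "regression")
    stop("predict_optima() requires a regression model")
  x <- coerce_features(model, x)
  out <- switch(model$architecture,
    nn = nn_forward(model, x),
    rf = vapply(model$fit, function(f)
      predict(f, data = x, num.threads = 1L)$predictions,
      numeric(nrow(x))),
    svm = vapply(model$fit, function(f)
      as.numeric(predict(f, newdata = x)), numeric(nrow(x))))
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(NULL, optimum_names(model$m)))
  out
}

#' @export
predict.divergence_model <- function(object, newdata, ...) {
  if (object$task == "classification") predict_labels(object, newdata)
  else predict_optima(object, newdata)
}
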