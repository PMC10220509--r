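#' Neural network configuration
#'
#' Architecture and optimizer settings for the dense feed-forward network.
#' The first hidden layer has `units_base` units and each subsequent hidden
#' layer half as many (256, 128, 64 for the default base).  Hidden units
#' use ReLU activations; the output layer is softmax for classification
#' (K = 2 class probabilities) and linear for regression (K = 2m optima).
#' With `hidden_layers = 0` the model reduces to logistic/linear
#' regression.  Weights are penalized by the elastic net
#' `lambda * sum((1 - gamma) * w^2 + gamma * abs(w))` over all inter-layer
#' weights (biases excluded), and training minimizes mean cross-entropy
#' (classification) or mean squared error (regression) plus that penalty
#' by mini-batch Adam.
#'
#' Default `lambda` and `gamma` are the cross-validation optima of the
#' benchmark's classification task; for regression the corresponding
#' optimum is `lambda = 7.499e-5`, `gamma = 1`.
#'
#' @param hidden_layers Number of hidden layers, 0 to 3.
#' @param lambda Elastic-net shrinkage, `>= 0`.
#' @param gamma Elastic-net L1/L2 mixing in `[0, 1]` (1 = pure lasso).
#' @param learning_rate,beta1,beta2 Adam step size and exponential decay
#'   rates of its first/second moment estimates.
#' @param batch_size Mini-batch size (the 20,000-observation benchmark uses
#'   5,000, i.e. 4 batches per epoch).
#' @param epochs Number of passes over the training data.
#' @param units_base Units in the first hidden layer.
#' @return An object of class `"nn_config"`.
#' @export
nn_config <- function(hidden_layers = 2L, lambda = 4.327e-4, gamma = 1,
                      learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      batch_size = 5000L, epochs = 500L,
                      units_base = 256L) {
  hidden_layers <- as.integer(hidden_layers)
  stopifnot(hidden_layers >= 0L, hidden_layers <= 3L,
            lambda >= 0, gamma >= 0, gamma <= 1,
            learning_rate > 0, batch_size >= 1L, epochs >= 1L,
            units_base >= 1L)
  units <- if (hidden_layers == 0L) integer(0) else
    as.integer(units_base / 2^(seq_len(hidden_layers) - 1))
  structure(list(hidden_layers = hidden_layers, units = units,
                 lambda = lambda, gamma = gamma,
                 learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 units_base = as.integer(units_base)),
            class = "nn_config")
}

#' Elastic-net penalty of a weight set
#'
#' `lambda * sum((1 - gamma) * w^2 + gamma * abs(w))` summed over every
#' inter-layer weight; bias terms are not penalized and must not be
#' included in `weights`.
#'
#' @param weights A numeric vector/matrix or a list of them (one entry per
#'   layer), bias terms excluded.
#' @param lambda Penalty strength, `>= 0`.
#' @param gamma L1/L2 mixing in `[0, 1]`.
#' @return The penalty value (a single number).
#' @examples
#' elastic_net_penalty(c(1, -2), lambda = 1, gamma = 1)    # |1| + |-2| = 3
#' elastic_net_penalty(c(1, -2), lambda = 0.5, gamma = 0)  # 0.5 * 5 = 2.5
#' @export
elastic_net_penalty <- function(weights, lambda, gamma) {
  stopifnot(lambda >= 0, gamma >= 0, gamma <= 1)
  if (!is.list(weights)) weights <- list(weights)
  sum(vapply(weights, function(w)
    lambda * sum((1 - gamma) * w^2 + gamma * abs(w)), numeric(1)))
}

response_matrix <- function(data, task) {
  if (task == "classification") {
    cbind(conserved = as.numeric(data$labels == "conserved"),
          diverged = as.numeric(data$labels == "diverged"))
  } else {
    cols <- as.vector(vapply(seq_len(data$m), function(k)
      paste0(c("theta1", "theta2"), "_c", k), character(2)))
    data$params[, cols, drop = FALSE]
  }
}

#' Train the neural network
#'
#' Fits the feed-forward network of [nn_config()] on a simulated dataset
#' by mini-batch Adam, minimizing mean cross-entropy (classification) or
#' mean squared error over all outputs (regression) plus the elastic-net
#' penalty.  Weight initialization is Glorot-uniform and mini-batches are
#' reshuffled every epoch; both draw from R's RNG, so a seed makes
#' training reproducible.
#'
#' @param data An `"ortholog_data"` training set.
#' @param task `"classification"` (conserved vs. diverged) or
#'   `"regression"` (the `2m` expression optima, ordered
#'   `theta1_c1, theta2_c1, ..., theta1_cm, theta2_cm`).
#' @param config An [nn_config()].
#' @param seed Optional integer seed.
#' @return A `"divergence_model"` object.
#' @export
train_nn <- function(data, task = c("classification", "regression"),
                     config = nn_config(), seed = NULL) {
  task <- match.arg(task)
  stopifnot(inherits(data, "ortholog_data"), nrow(data$features) > 0)
  if (!is.null(seed)) set.seed(seed)
  Y <- response_matrix(data, task)
  fit <- nn_train_cpp(data$features, Y, config$units,
                      classify = task == "classification",
                      lambda = config$lambda, gamma = config$gamma,
                      lr = config$learning_rate,
                      beta1 = config$beta1, beta2 = config$beta2,
                      batch_size = min(config$batch_size,
                                       nrow(data$features)),
                      epochs = config$epochs)
  new_divergence_model("nn", task, fit, config, data$m,
                       colnames(data$features),
                       output_names = colnames(Y), seed = seed)
}

#' Forward pass of a trained network
#'
#' @param model A `"divergence_model"` with architecture `"nn"`.
#' @param x A feature matrix (rows = ortholog pairs) or a single feature
#'   vector of length `2m`.
#' @return A matrix of class probabilities (rows summing to 1) or optimum
#'   estimates.
#' @export
nn_forward <- function(model, x) {
  stopifnot(inherits(model, "divergence_model"),
            model$architecture == "nn")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != 2 * model$m)
    stop("feature matrix has ", ncol(x), " columns; expected ", 2 * model$m)
  out <- nn_forward_cpp(x, model$fit$weights, model$fit$biases,
                        classify = model$task == "classification")
  colnames(out) <- model$output_names
  out
}

mean_cross_entropy <- function(prob, y_onehot) {
  -mean(rowSums(y_onehot * log(prob + 1e-12)))
}

balanced_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

subset_data <- function(data, idx) {
  structure(list(features = data$features[idx, , drop = FALSE],
                 labels = droplevels_keep(data$labels[idx]),
                 params = data$params[idx, , drop = FALSE],
                 m = data$m, prior = data$prior, seed = data$seed,
                 n_conserved = sum(data$labels[idx] == "conserved"),
                 n_diverged = sum(data$labels[idx] == "diverged")),
            class = "ortholog_data")
}

droplevels_keep <- function(x) factor(x, levels = class_levels)

#' Cross-validated loss of one network configuration
#'
#' Runs class-balanced k-fold cross-validation (80/20 splits for the
#' default 5 folds).  The reported validation loss is the full training
#' objective evaluated on the held-out fold: mean cross-entropy
#' (classification) or per-element mean squared error (regression) *plus*
#' the elastic-net penalty of the fold's fitted weights — the same
#' quantity mini-batch training minimizes, and the one a deep-learning
#' workflow prints as validation loss.  The unpenalized components are
#' returned alongside.
#'
#' @inheritParams train_nn
#' @param folds Number of folds.
#' @param seed Optional seed controlling fold assignment and training.
#' @return A list with `mean_loss`, per-fold `fold_loss`, and the
#'   unpenalized `mean_data_loss` / `mean_penalty` components.
#' @export
cv_nn <- function(data, task = c("classification", "regression"),
                  config = nn_config(), folds = 5L, seed = NULL) {
  task <- match.arg(task)
  if (!is.null(seed)) set.seed(seed)
  fold <- balanced_folds(data$labels, folds)
  parts <- vapply(seq_len(folds), function(f) {
    train <- subset_data(data, fold != f)
    valid <- subset_data(data, fold == f)
    model <- train_nn(train, task, config)
    pred <- nn_forward(model, valid$features)
    Yv <- response_matrix(valid, task)
    data_loss <- if (task == "classification") mean_cross_entropy(pred, Yv)
      else mean((pred - Yv)^2)
    c(data_loss,
      elastic_net_penalty(model$fit$weights, config$lambda, config$gamma))
  }, numeric(2))
  list(mean_loss = mean(parts[1, ] + parts[2, ]),
       fold_loss = parts[1, ] + parts[2, ],
       mean_data_loss = mean(parts[1, ]),
       mean_penalty = mean(parts[2, ]))
}

#' Grid-search the network hyperparameters by cross-validation
#'
#' Evaluates every combination of hidden-layer count, `lambda`, and
#' `gamma` by [cv_nn()] and returns the configuration minimizing mean
#' validation loss, refit on the full dataset.  The benchmark grid is
#' `hidden_layers` 0-3, 25 `lambda` values log-uniform on
#' `log10(lambda) in [-12, -3]`, and `gamma` 0, 0.1, ..., 1; that full
#' grid is expensive, so smaller grids, a row subsample, and a reduced
#' epoch count can be supplied for exploratory selection.
#'
#' @inheritParams cv_nn
#' @param hidden_layers_grid,lambda_grid,gamma_grid Candidate values.
#' @param n_subsample Optional number of rows (class-balanced) to
#'   subsample before cross-validating, for cheaper selection.
#' @param epochs Optional override of `config$epochs` during selection
#'   (the final refit always uses `config$epochs`).
#' @return A list with `config` (best configuration), `model` (refit on
#'   all of `data`), `cv` (a data.frame of the grid with mean losses), and
#'   `best_loss`.
#' @export
tune_nn <- function(data, task = c("classification", "regression"),
                    hidden_layers_grid = 0:3,
                    lambda_grid = 10^seq(-12, -3, length.out = 25),
                    gamma_grid = seq(0, 1, by = 0.1),
                    config = nn_config(), folds = 5L,
                    n_subsample = NULL, epochs = NULL, seed = NULL) {
  task <- match.arg(task)
  if (length(hidden_layers_grid) == 0 || length(lambda_grid) == 0 ||
      length(gamma_grid) == 0)
    stop("empty hyperparameter grid")
  if (!is.null(seed)) set.seed(seed)
  cv_data <- data
  if (!is.null(n_subsample) && n_subsample < nrow(data$features)) {
    fold <- balanced_folds(data$labels,
                           floor(nrow(data$features) / n_subsample))
    cv_data <- subset_data(data, fold == 1L)
  }
  grid <- expand.grid(hidden_layers = hidden_layers_grid,
                      lambda = lambda_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$loss <- NA_real_
  cfg_for <- function(row, n_epochs) {
    cfg <- config
    cfg$hidden_layers <- as.integer(row$hidden_layers)
    cfg$units <- if (cfg$hidden_layers == 0L) integer(0) else
      as.integer(cfg$units_base / 2^(seq_len(cfg$hidden_layers) - 1))
    cfg$lambda <- row$lambda
    cfg$gamma <- row$gamma
    if (!is.null(n_epochs)) cfg$epochs <- as.integer(n_epochs)
    cfg
  }
  for (i in seq_len(nrow(grid))) {
    grid$loss[i] <- cv_nn(cv_data, task, cfg_for(grid[i, ], epochs),
                          folds = folds)$mean_loss
  }
  best <- which.min(grid$loss)
  best_config <- cfg_for(grid[best, ], NULL)
  model <- train_nn(data, task, best_config)
  list(config = best_config, model = model, cv = grid,
       best_loss = grid$loss[best])
}
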