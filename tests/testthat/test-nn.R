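test_that("elastic-net penalty arithmetic and monotonicity", {
  w <- c(1, -2)
  expect_equal(elastic_net_penalty(w, lambda = 0, gamma = 0.5), 0)
  expect_equal(elastic_net_penalty(w, lambda = 1, gamma = 1), 3)
  expect_equal(elastic_net_penalty(w, lambda = 0.5, gamma = 0), 2.5)
  # list form sums over layers
  expect_equal(elastic_net_penalty(list(w, w), 1, 1), 6)
  # nondecreasing in lambda for fixed weights
  lams <- seq(0, 2, by = 0.25)
  pen <- vapply(lams, function(l) elastic_net_penalty(w, l, 0.3),
                numeric(1))
  expect_true(all(diff(pen) >= 0))
})

manual_model <- function(weights, biases, task, m) {
  cfg <- nn_config(hidden_layers = length(weights) - 1L,
                   units_base = if (length(weights) > 1)
                     ncol(weights[[1]]) else 256L)
  oudiverge:::new_divergence_model(
    "nn", task, list(weights = weights, biases = biases), cfg, m,
    oudiverge:::feature_names(m),
    output_names = if (task == "classification")
      c("conserved", "diverged") else oudiverge:::optimum_names(m))
}

test_that("forward pass matches hand arithmetic", {
  # zero weights and biases: softmax of equal logits is (0.5, 0.5)
  m0 <- manual_model(list(matrix(0, 2, 2)), list(matrix(0, 1, 2)),
                     "classification", m = 1)
  expect_equal(as.numeric(nn_forward(m0, c(1, 2))), c(0.5, 0.5))

  # one hidden layer, hand-set weights
  W1 <- matrix(c(1, -1, 0.5, 2), 2, 2)   # 2 inputs -> 2 hidden
  b1 <- matrix(c(0.1, -0.2), 1, 2)
  W2 <- matrix(c(1, 0.5, -1, 0.25), 2, 2)
  b2 <- matrix(c(0, 0.3), 1, 2)
  mod <- manual_model(list(W1, W2), list(b1, b2), "classification", m = 1)
  x <- c(0.7, -0.3)
  h <- pmax(as.vector(x %*% W1) + as.vector(b1), 0)
  logits <- as.vector(h %*% W2) + as.vector(b2)
  probs <- exp(logits) / sum(exp(logits))
  expect_equal(as.numeric(nn_forward(mod, x)), unname(probs),
               tolerance = 1e-12)

  # a hidden unit with negative pre-activation contributes nothing
  W1d <- matrix(c(1, 0, 0, 1), 2, 2)
  b1d <- matrix(c(-10, 0), 1, 2)  # unit 1 dead for small inputs
  W2d <- matrix(c(100, 1, -100, -1), 2, 2)
  modd <- manual_model(list(W1d, W2d), list(b1d, matrix(0, 1, 2)),
                       "classification", m = 1)
  xd <- c(0.5, 0.2)
  h2 <- 0.2  # only unit 2 fires
  expect_equal(unname(nn_forward(modd, xd))[2] -
                 exp(-h2) / (exp(h2) + exp(-h2)), 0, tolerance = 1e-12)

  # regression head is linear (m = 1 predicts the two optima)
  modr <- manual_model(list(matrix(c(1, 2, 0, 1), 2, 2)),
                       list(matrix(c(0.5, 0), 1, 2)), "regression", m = 1)
  expect_equal(as.numeric(nn_forward(modr, c(3, 4))), c(11.5, 4))
})

test_that("classification probabilities sum to one", {
  d <- simulate_dataset(prior_spec(), 100, 100, seed = 20)
  nn <- train_nn(d, "classification",
                 nn_config(epochs = 30, batch_size = 100), seed = 21)
  pr <- nn_forward(nn, d$features)
  expect_true(all(abs(rowSums(pr) - 1) < 1e-9))
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("training is reproducible under a seed", {
  d <- simulate_dataset(prior_spec(), 80, 80, seed = 22)
  cfg <- nn_config(epochs = 20, batch_size = 80)
  a <- train_nn(d, "classification", cfg, seed = 23)
  b <- train_nn(d, "classification", cfg, seed = 23)
  expect_identical(a$fit$weights, b$fit$weights)
  c <- train_nn(d, "classification", cfg, seed = 24)
  expect_false(identical(a$fit$weights, c$fit$weights))
})

test_that("a separable toy problem is classified perfectly", {
  toy <- toy_separable()
  nn <- train_nn(toy, "classification",
                 nn_config(epochs = 100, batch_size = 60), seed = 25)
  pred <- predict_labels(nn, toy$features)
  expect_equal(accuracy(pred$label, toy$labels), 1.0)
})

test_that("no-signal training data gives chance-level accuracy", {
  # force theta2 == theta1 in both classes: labels carry no information
  set.seed(26)
  d <- simulate_dataset(prior_spec(), 400, 0, seed = 26)
  d2 <- simulate_dataset(prior_spec(), 400, 0, seed = 27)
  d2$labels[] <- "diverged"
  train <- merge_datasets(d, d2)
  test_c <- simulate_dataset(prior_spec(), 200, 0, seed = 28)
  test_d <- simulate_dataset(prior_spec(), 200, 0, seed = 29)
  test_d$labels[] <- "diverged"
  test <- merge_datasets(test_c, test_d)
  nn <- train_nn(train, "classification",
                 nn_config(epochs = 60, batch_size = 400), seed = 30)
  pred <- predict_labels(nn, test$features)
  expect_lt(abs(accuracy(pred$label, test$labels) - 0.5), 0.12)
})

test_that("a zero-hidden-layer unpenalized network matches logistic regression", {
  set.seed(31)
  n <- 300
  x <- cbind(e1_c1 = rnorm(n), e2_c1 = rnorm(n))
  lab <- factor(ifelse(x[, 1] - x[, 2] + rnorm(n, sd = 0.3) > 0,
                       "diverged", "conserved"),
                levels = c("conserved", "diverged"))
  d <- structure(list(features = x, labels = lab,
                      params = matrix(0, n, 4), m = 1L,
                      prior = prior_spec(m = 1), seed = NULL,
                      n_conserved = sum(lab == "conserved"),
                      n_diverged = sum(lab == "diverged")),
                 class = "ortholog_data")
  nn <- train_nn(d, "classification",
                 nn_config(hidden_layers = 0, lambda = 0,
                           learning_rate = 0.01, epochs = 4000,
                           batch_size = n), seed = 32)
  glm_fit <- suppressWarnings(glm(lab ~ x, family = binomial()))
  glm_lab <- ifelse(fitted(glm_fit) > 0.5, "diverged", "conserved")
  nn_lab <- predict_labels(nn, x)$label
  expect_gte(mean(as.character(nn_lab) == glm_lab), 0.99)
})

test_that("degenerate tuning grids are honoured", {
  d <- simulate_dataset(prior_spec(m = 2), 50, 50, seed = 33)
  res <- tune_nn(d, "classification", hidden_layers_grid = 1,
                 lambda_grid = 1e-4, gamma_grid = 1,
                 config = nn_config(epochs = 10, batch_size = 50),
                 seed = 34)
  expect_equal(res$config$hidden_layers, 1L)
  expect_equal(res$config$lambda, 1e-4)
  expect_equal(nrow(res$cv), 1)
  expect_identical(res$best_loss, res$cv$loss[1])
  expect_error(tune_nn(d, "classification", hidden_layers_grid = integer(0)),
               "empty")
})
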