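test_that("random forest handles uninformative and separable data", {
  # constant features: every prediction falls back to the majority class
  n <- 120
  d <- structure(list(
    features = matrix(1, n, 4,
                      dimnames = list(NULL, oudiverge:::feature_names(2))),
    labels = factor(rep(c("conserved", "diverged"), c(80, 40)),
                    levels = c("conserved", "diverged")),
    params = matrix(0, n, 8), m = 2L, prior = prior_spec(m = 2),
    seed = NULL, n_conserved = 80, n_diverged = 40),
    class = "ortholog_data")
  rf <- train_rf(d, "classification", rf_config(num_trees = 50), seed = 40)
  pred <- predict_labels(rf, d$features)
  expect_true(all(pred$label == "conserved"))

  toy <- toy_separable()
  rf2 <- train_rf(toy, "classification", rf_config(), seed = 41)
  expect_equal(accuracy(predict_labels(rf2, toy$features)$label,
                        toy$labels), 1.0)
})

test_that("svm separates a toy problem and respects two-point geometry", {
  toy <- toy_separable()
  svm <- train_svm(toy, "classification", svm_config(gamma = 0.1, cost = 10),
                   seed = 42)
  expect_equal(accuracy(predict_labels(svm, toy$features)$label,
                        toy$labels), 1.0)

  # with a nearly linear kernel the separable toy stays perfect
  svm_lin <- train_svm(toy, "classification",
                       svm_config(gamma = 1e-4, cost = 100), seed = 43)
  expect_equal(accuracy(predict_labels(svm_lin, toy$features)$label,
                        toy$labels), 1.0)

  # two points, one per class: both are support vectors and the decision
  # boundary lies midway between them
  d2 <- structure(list(
    features = matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE,
                      dimnames = list(NULL, oudiverge:::feature_names(1))),
    labels = factor(c("conserved", "diverged"),
                    levels = c("conserved", "diverged")),
    params = matrix(0, 2, 4), m = 1L, prior = prior_spec(m = 1),
    seed = NULL, n_conserved = 1, n_diverged = 1),
    class = "ortholog_data")
  svm2 <- train_svm(d2, "classification", svm_config(gamma = 1, cost = 10))
  expect_equal(nrow(svm2$fit$SV), 2)
  mid <- predict_labels(svm2, c(0.5, 0.5))
  expect_lt(abs(mid$score), 1e-6)
  expect_equal(as.character(mid$label), "conserved")  # tie rule
})

test_that("svm tuning returns members of its grids", {
  d <- simulate_dataset(prior_spec(m = 2), 60, 60, seed = 44)
  gg <- c(0.01, 0.1)
  cg <- c(0.5, 5)
  res <- tune_svm(d, "classification", gamma_grid = gg, cost_grid = cg,
                  folds = 3, seed = 45)
  expect_true(res$config$gamma %in% gg)
  expect_true(res$config$cost %in% cg)
  expect_equal(nrow(res$cv), 4)
  single <- tune_svm(d, "classification", gamma_grid = 0.2, cost_grid = 2,
                     folds = 3, seed = 46)
  expect_equal(single$config$gamma, 0.2)
  expect_equal(single$config$cost, 2)
  expect_error(tune_svm(d, "classification", gamma_grid = numeric(0)),
               "empty")
})

test_that("regression predictors return the 2m optima in order", {
  d <- simulate_dataset(prior_spec(), 80, 80, seed = 47)
  for (fit in list(
    train_rf(d, "regression", rf_config(num_trees = 30), seed = 48),
    train_svm(d, "regression", svm_config(gamma = 0.1, cost = 1),
              seed = 49))) {
    est <- predict_optima(fit, d$features[1:10, ])
    expect_equal(dim(est), c(10, 12))
    expect_identical(colnames(est)[1:4],
                     c("theta1_c1", "theta2_c1", "theta1_c2", "theta2_c2"))
  }
  nnr <- train_nn(d, "regression",
                  nn_config(lambda = 7.499e-5, epochs = 30,
                            batch_size = 160), seed = 50)
  est <- predict_optima(nnr, d$features)
  expect_equal(dim(est), c(160, 12))
})

test_that("task and shape mismatches are rejected", {
  d <- simulate_dataset(prior_spec(m = 2), 30, 30, seed = 51)
  clf <- train_rf(d, "classification", rf_config(num_trees = 20), seed = 52)
  reg <- train_rf(d, "regression", rf_config(num_trees = 20), seed = 53)
  expect_error(predict_optima(clf, d$features), "regression")
  expect_error(predict_labels(reg, d$features), "classification")
  expect_error(predict_labels(clf, d$features[, 1:3]), "columns")
})

test_that("conserved optima are recovered more tightly than diverged ones", {
  set.seed(54)
  train <- simulate_dataset(prior_spec(m = 2), 800, 800, seed = 55)
  test <- simulate_dataset(prior_spec(m = 2), 300, 300, seed = 56)
  nnr <- train_nn(train, "regression",
                  nn_config(lambda = 7.499e-5, epochs = 150,
                            batch_size = 800), seed = 57)
  est <- predict_optima(nnr, test$features)
  truth <- test$params[, c(1, 2, 5, 6)]
  err <- abs(est - truth)
  cons <- test$labels == "conserved"
  expect_lt(median(err[cons, ]), median(err[!cons, ]))
})
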