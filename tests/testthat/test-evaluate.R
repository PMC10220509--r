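test_that("accuracy and confusion rates on hand-checkable inputs", {
  truth <- factor(c("conserved", "conserved", "diverged", "diverged"))
  expect_equal(accuracy(truth, truth), 1.0)
  half <- factor(c("conserved", "diverged", "diverged", "conserved"))
  expect_equal(accuracy(half, truth), 0.5)
  expect_error(accuracy(character(0), character(0)))

  cm <- confusion_rates(truth, truth)
  expect_equal(unname(cm), diag(2))
  cm2 <- confusion_rates(half, truth)
  expect_true(all(abs(rowSums(cm2) - 1) < 1e-9))
  expect_true(all(cm2 >= 0 & cm2 <= 1))
})

test_that("accuracy equals the class-prior-weighted trace of the confusion matrix", {
  set.seed(70)
  for (i in 1:10) {
    truth <- factor(sample(c("conserved", "diverged"), 200, replace = TRUE,
                           prob = c(0.7, 0.3)),
                    levels = c("conserved", "diverged"))
    pred <- factor(sample(c("conserved", "diverged"), 200, replace = TRUE),
                   levels = c("conserved", "diverged"))
    cm <- confusion_rates(pred, truth)
    priors <- prop.table(table(truth))
    expect_equal(accuracy(pred, truth),
                 sum(diag(cm) * as.numeric(priors)))
  }
})

test_that("roc curve endpoints, chance level, and frozen example", {
  # perfectly separating scores
  truth <- factor(rep(c("conserved", "diverged"), each = 50))
  r <- roc_curve(c(runif(50, 0, 0.4), runif(50, 0.6, 1)), truth)
  expect_equal(r$auc, 1.0)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))

  # label-independent scores sit at AUC 1/2
  set.seed(71)
  big <- factor(sample(c("conserved", "diverged"), 1e5, replace = TRUE))
  r2 <- roc_curve(runif(1e5), big)
  expect_lt(abs(r2$auc - 0.5), 0.01)

  # enumerated small case: diverged scores {0.9, 0.8, 0.2} vs conserved
  # {0.4} -> 2 of 3 pairs concordant
  r3 <- roc_curve(c(0.9, 0.8, 0.4, 0.2),
                  c("diverged", "diverged", "conserved", "diverged"))
  expect_equal(r3$auc, 2 / 3)

  expect_error(roc_curve(1:4, rep("diverged", 4)), "both classes")
})

test_that("trapezoid AUC equals brute-force concordance, ties included", {
  set.seed(72)
  for (i in 1:8) {
    n <- sample(20:60, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    truth <- factor(sample(c("conserved", "diverged"), n, replace = TRUE),
                    levels = c("conserved", "diverged"))
    if (nlevels(droplevels(truth)) < 2) next
    expect_equal(roc_curve(scores, truth)$auc,
                 auc_by_enumeration(scores, truth))
  }
})

test_that("auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(73)
  scores <- rnorm(400)
  truth <- factor(ifelse(scores + rnorm(400) > 0, "diverged", "conserved"),
                  levels = c("conserved", "diverged"))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("conserved", "diverged"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_curve(scores, truth)$auc, ref, tolerance = 1e-12)
})

test_that("optimum-error summaries split by parameter, condition, and class", {
  set.seed(74)
  truth <- matrix(runif(40 * 4, 0, 5), 40, 4)
  labels <- factor(rep(c("conserved", "diverged"), 20),
                   levels = c("conserved", "diverged"))
  s0 <- optima_error_summary(truth, truth, labels)
  expect_equal(nrow(s0), 2 * 2 * 2)  # parameter x condition x class
  expect_true(all(s0$median_error == 0))
  expect_true(all(s0$iqr == 0))
  s1 <- optima_error_summary(truth + 1, truth, labels)
  expect_true(all(s1$median_error == 1))
  expect_error(optima_error_summary(truth[, 1:2], truth, labels))
})

test_that("regime sweep emits one row per method and regime", {
  toy <- toy_separable(n_per_class = 40)
  rf <- train_rf(toy, "classification", rf_config(num_trees = 30),
                 seed = 75)
  base <- calibrate_cutoff(toy, "manhattan", "absolute", seed = 76)
  sweep <- regime_sweep(list(rf = rf, distance = base),
                        alpha_ranges = list(c(1, 10), c(100, 1000)),
                        sigma2_ranges = list(c(0.01, 0.1)),
                        n_per_class = 50, seed = 77)
  expect_equal(nrow(sweep), 2 * 2)
  expect_setequal(unique(sweep$method), c("rf", "distance"))
  expect_true(all(sweep$accuracy >= 0 & sweep$accuracy <= 1))
  expect_true(all(sweep$auc >= 0 & sweep$auc <= 1))
})
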