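#' Classification accuracy
#'
#' @param predicted,truth Label vectors of equal, nonzero length.
#' @return Fraction of exact matches.
#' @export
accuracy <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) > 0)
  mean(as.character(predicted) == as.character(truth))
}

#' Row-normalized confusion matrix
#'
#' Rows index the true class, columns the predicted class; each row sums
#' to one, so the main diagonal holds the per-class correct-classification
#' rates.
#'
#' @inheritParams accuracy
#' @return A 2x2 numeric matrix with dimnames `truth` x `predicted`.
#' @export
confusion_rates <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) > 0)
  predicted <- factor(as.character(predicted), levels = class_levels)
  truth <- factor(as.character(truth), levels = class_levels)
  if (nlevels(droplevels(truth)) < 2)
    stop("both classes must be present in truth")
  counts <- table(truth = truth, predicted = predicted)
  rates <- counts / rowSums(counts)
  matrix(rates, 2, 2, dimnames = dimnames(counts))
}

#' Receiver operating characteristic curve
#'
#' Sweeps all score thresholds ("diverged" is the positive class; higher
#' scores mean more diverged), grouping tied scores into a single step,
#' and computes the area under the curve by the trapezoid rule — which
#' gives tied scores half credit, so the AUC equals the
#' concordance probability between a random diverged/conserved pair.
#'
#' @param scores Numeric divergence scores.
#' @param truth Labels (`"conserved"`/`"diverged"`).
#' @return An object of class `"roc_curve"`: list with `points` (a
#'   data.frame of `fpr`, `tpr` a.k.a. power) and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  pos <- as.character(truth) == "diverged"
  if (!any(pos) || all(pos))
    stop("both classes must be present in truth")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # indices closing each tie block
  last <- which(!duplicated(s, fromLast = TRUE))
  tpr <- c(0, cumsum(p)[last] / sum(pos))
  fpr <- c(0, cumsum(!p)[last] / sum(!pos))
  auc <- sum(diff(fpr) * (head_(tpr) + diff(tpr) / 2))
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

head_ <- function(x) x[-length(x)]

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Summarize expression-optimum prediction errors
#'
#' Splits the signed errors (estimate minus truth) by parameter (`theta1`
#' vs. `theta2`), condition, and true class, reporting the median and
#' interquartile range of each cell.
#'
#' @param estimates,truth `N` x `2m` matrices ordered
#'   `theta1_c1, theta2_c1, ...`.
#' @param labels True class labels of the `N` records.
#' @return A `data.frame` with columns `parameter`, `condition`, `class`,
#'   `median_error`, `iqr`.
#' @export
optima_error_summary <- function(estimates, truth, labels) {
  stopifnot(all(dim(estimates) == dim(truth)),
            nrow(estimates) == length(labels))
  m <- ncol(estimates) / 2
  err <- estimates - truth
  grid <- expand.grid(parameter = c("theta1", "theta2"),
                      condition = seq_len(m),
                      class = class_levels,
                      KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  stats <- t(apply(grid, 1, function(g) {
    col <- 2 * (as.integer(g[["condition"]]) - 1) +
      if (g[["parameter"]] == "theta1") 1 else 2
    e <- err[as.character(labels) == g[["class"]], col]
    c(median(e), unname(diff(quantile(e, c(0.25, 0.75)))))
  }))
  grid$median_error <- stats[, 1]
  grid$iqr <- stats[, 2]
  grid
}

#' Benchmark trained classifiers across restricted parameter regimes
#'
#' Simulates one balanced test set per (alpha-range, sigma2-range)
#' rectangle — `alpha` and `sigma2` drawn linear-uniformly inside the
#' regime, as in the restricted-regime evaluation — and applies each
#' supplied classifier, reporting accuracy, power (diverged-class true
#' positive rate), and AUC.
#'
#' @param models Named list of classification `"divergence_model"` and/or
#'   calibrated `"distance_config"` objects (trained on the full prior).
#' @param alpha_ranges,sigma2_ranges Lists of 2-vectors delimiting the
#'   regimes; defaults are the 3 x 5 benchmark rectangles.
#' @param base The full [prior_spec()] the models were trained under.
#' @param n_per_class Test observations simulated per class per regime.
#' @param seed Optional seed.
#' @return A `data.frame` with one row per (method, regime).
#' @export
regime_sweep <- function(models,
                         alpha_ranges = list(c(1, 10), c(10, 100),
                                             c(100, 1000)),
                         sigma2_ranges = list(c(0.01, 0.1), c(0.1, 1),
                                              c(1, 10), c(10, 100),
                                              c(100, 1000)),
                         base = prior_spec(), n_per_class = 1000L,
                         seed = NULL) {
  stopifnot(length(models) > 0, !is.null(names(models)))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (ar in alpha_ranges) {
    for (sr in sigma2_ranges) {
      test <- simulate_dataset(regime_prior(ar, sr, base),
                               n_per_class, n_per_class)
      for (nm in names(models)) {
        pred <- if (inherits(models[[nm]], "distance_config"))
          classify_by_distance(test$features, models[[nm]])
        else predict_labels(models[[nm]], test$features)
        cm <- confusion_rates(pred$label, test$labels)
        rows[[length(rows) + 1L]] <- data.frame(
          method = nm, alpha_min = ar[1], alpha_max = ar[2],
          sigma2_min = sr[1], sigma2_max = sr[2],
          accuracy = accuracy(pred$label, test$labels),
          power = cm["diverged", "diverged"],
          auc = roc_curve(pred$score, test$labels)$auc)
      }
    }
  }
  do.call(rbind, rows)
}
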