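#' Distance-based baseline classifier configuration
#'
#' The comparison classifier labels an ortholog pair "diverged" when the
#' distance between the two species' m-condition expression profiles
#' exceeds a cutoff `c`.  Four variants are supported: Euclidean or
#' Manhattan distance, on absolute profiles (the log-expression vectors as
#' given) or relative profiles (each species' vector centered by its own
#' mean across conditions, which removes overall expression level and
#' keeps profile shape).
#'
#' @param metric `"manhattan"` or `"euclidean"`.
#' @param representation `"absolute"` or `"relative"`.
#' @param cutoff Decision cutoff `c >= 0`; usually set by
#'   [calibrate_cutoff()].
#' @return An object of class `"distance_config"`.
#' @export
distance_config <- function(metric = c("manhattan", "euclidean"),
                            representation = c("absolute", "relative"),
                            cutoff = NULL) {
  metric <- match.arg(metric)
  representation <- match.arg(representation)
  if (!is.null(cutoff)) stopifnot(is.finite(cutoff), cutoff >= 0)
  structure(list(metric = metric, representation = representation,
                 cutoff = cutoff),
            class = "distance_config")
}

#' Split a feature matrix into per-species expression profiles
#'
#' @param x Feature matrix (or single vector) with `2m` interleaved
#'   columns `e1_c1, e2_c1, ...`.
#' @param representation `"absolute"` keeps the log-expression vectors as
#'   given; `"relative"` centers each species' vector by its own mean
#'   across conditions.
#' @return A list with matrices `species1` and `species2` (`N` x `m`).
#' @export
species_profiles <- function(x, representation = c("absolute", "relative")) {
  representation <- match.arg(representation)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) %% 2 == 0)
  m <- ncol(x) / 2
  s1 <- x[, seq(1, 2 * m, by = 2), drop = FALSE]
  s2 <- x[, seq(2, 2 * m, by = 2), drop = FALSE]
  if (representation == "relative") {
    s1 <- s1 - rowMeans(s1)
    s2 <- s2 - rowMeans(s2)
  }
  list(species1 = s1, species2 = s2)
}

#' Distance between the two species' expression profiles
#'
#' @inheritParams species_profiles
#' @param metric `"manhattan"` (L1) or `"euclidean"` (L2).
#' @return Numeric vector of nonnegative distances, one per row of `x`.
#' @examples
#' x <- rep(c(0, 1), 6)  # species 2 one unit higher in all 6 conditions
#' expression_distance(x, "manhattan", "absolute")  # 6
#' expression_distance(x, "euclidean", "absolute")  # sqrt(6)
#' @export
expression_distance <- function(x, metric = c("manhattan", "euclidean"),
                                representation = c("absolute", "relative")) {
  metric <- match.arg(metric)
  pr <- species_profiles(x, representation)
  diff <- pr$species1 - pr$species2
  if (metric == "manhattan") rowSums(abs(diff))
  else sqrt(rowSums(diff^2))
}

#' Calibrate the distance cutoff by cross-validation
#'
#' Takes 100 candidate cutoffs uniformly spaced over the observed range of
#' training distances and picks the one maximizing mean validation
#' accuracy across class-balanced k folds (ties resolve to the smallest
#' cutoff).
#'
#' @param data An `"ortholog_data"` training set with both classes.
#' @inheritParams expression_distance
#' @param folds Number of cross-validation folds.
#' @param n_cutoffs Number of candidate cutoffs.
#' @param seed Optional seed controlling fold assignment.
#' @return A calibrated [distance_config()] with extra fields
#'   `cv_accuracy` (mean validation accuracy at the chosen cutoff) and
#'   `candidates` (the cutoff grid).
#' @export
calibrate_cutoff <- function(data, metric = c("manhattan", "euclidean"),
                             representation = c("absolute", "relative"),
                             folds = 5L, n_cutoffs = 100L, seed = NULL) {
  metric <- match.arg(metric)
  representation <- match.arg(representation)
  stopifnot(inherits(data, "ortholog_data"))
  if (nlevels(droplevels(data$labels)) < 2)
    stop("cutoff calibration needs both classes in the training data")
  if (!is.null(seed)) set.seed(seed)
  d <- expression_distance(data$features, metric, representation)
  cutoffs <- seq(min(d), max(d), length.out = n_cutoffs)
  fold <- balanced_folds(data$labels, folds)
  diverged <- data$labels == "diverged"
  acc <- vapply(seq_len(folds), function(f) {
    dv <- d[fold == f]
    truth <- diverged[fold == f]
    vapply(cutoffs, function(c) mean((dv > c) == truth), numeric(1))
  }, numeric(n_cutoffs))
  mean_acc <- rowMeans(acc)
  best <- which.max(mean_acc)  # which.max takes the first (smallest) tie
  cfg <- distance_config(metric, representation, cutoff = cutoffs[best])
  cfg$cv_accuracy <- mean_acc[best]
  cfg$candidates <- cutoffs
  cfg
}

#' Classify ortholog pairs by expression distance
#'
#' Labels a pair "diverged" when its profile distance exceeds the
#' calibrated cutoff (a distance exactly at the cutoff stays
#' "conserved"); the raw distance is returned as the score for ROC
#' analysis.
#'
#' @inheritParams species_profiles
#' @param config A calibrated [distance_config()].
#' @return A `data.frame` with columns `label` and `score`.
#' @export
classify_by_distance <- function(x, config) {
  stopifnot(inherits(config, "distance_config"))
  if (is.null(config$cutoff))
    stop("distance config has no cutoff; run calibrate_cutoff() first")
  d <- expression_distance(x, config$metric, config$representation)
  data.frame(label = factor(ifelse(d > config$cutoff,
                                   "diverged", "conserved"),
                            levels = class_levels),
             score = d)
}
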