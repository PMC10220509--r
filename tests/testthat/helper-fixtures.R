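# Shared benchmark fixtures: the standard simulated train/test sets and the
# models trained on them.  Training the full-scale models is expensive, so
# each is built once on first use and cached for the whole test run.

fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixtures[[name]])) fixtures[[name]] <- builder()
  fixtures[[name]]
}

std_train <- function() {
  fixture("train", function()
    simulate_dataset(prior_spec(), 10000, 10000, seed = 210))
}

std_test <- function() {
  fixture("test", function()
    simulate_dataset(prior_spec(), 1000, 1000, seed = 211))
}

std_nn <- function() {
  fixture("nn", function()
    train_nn(std_train(), "classification", nn_config(), seed = 212))
}

std_nn_reg <- function() {
  fixture("nn_reg", function()
    train_nn(std_train(), "regression",
             nn_config(lambda = 7.499e-5, gamma = 1), seed = 213))
}

std_rf <- function() {
  fixture("rf", function()
    train_rf(std_train(), "classification", rf_config(), seed = 214))
}

std_svm <- function() {
  fixture("svm", function()
    tune_svm(std_train(), "classification",
             gamma_grid = svm_gamma_grid(),
             cost_grid = c(0.1, 1, 10),
             n_subsample = 4000, seed = 215)$model)
}

std_baseline <- function() {
  fixture("baseline", function()
    calibrate_cutoff(std_train(), "manhattan", "absolute", seed = 216))
}

# tiny toy set in which the diverged class is offset by +5 in every
# condition of species 2: linearly separable by construction
toy_separable <- function(n_per_class = 60, m = 6, seed = 42) {
  set.seed(seed)
  prior <- prior_spec(m = m)
  cons <- simulate_dataset(regime_prior(c(900, 1000), c(0.01, 0.02), prior),
                           n_per_class, 0)
  div <- simulate_dataset(regime_prior(c(900, 1000), c(0.01, 0.02), prior),
                          n_per_class, 0)
  div$features[, seq(2, 2 * m, by = 2)] <-
    div$features[, seq(2, 2 * m, by = 2)] + 5
  div$labels[] <- "diverged"
  merge_datasets(cons, div)
}

merge_datasets <- function(a, b) {
  structure(list(features = rbind(a$features, b$features),
                 labels = factor(c(as.character(a$labels),
                                   as.character(b$labels)),
                                 levels = c("conserved", "diverged")),
                 params = rbind(a$params, b$params),
                 m = a$m, prior = a$prior, seed = NULL,
                 n_conserved = sum(c(a$labels, b$labels) == 1),
                 n_diverged = sum(c(a$labels, b$labels) == 2)),
            class = "ortholog_data")
}

# exact AUC by pair enumeration (ties get half credit)
auc_by_enumeration <- function(scores, truth) {
  pos <- scores[truth == "diverged"]
  neg <- scores[truth == "conserved"]
  total <- 0
  for (s in pos)
    total <- total + sum(s > neg) + 0.5 * sum(s == neg)
  total / (length(pos) * length(neg))
}

# two-tailed binomial P by full enumeration (outcomes with point
# probability <= observed, with the customary 1 + 1e-7 relative guard)
binom_p_by_enumeration <- function(x, n, p) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# two-tailed Fisher P for a 2x2 table by hypergeometric enumeration
fisher_p_by_enumeration <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  d <- dhyper(support, m, n, k)
  sum(d[d <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
}
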