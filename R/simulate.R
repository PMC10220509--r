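#' Prior specification for simulating ortholog expression data
#'
#' Describes the distributions from which per-condition OU parameters are
#' drawn.  Defaults reproduce the benchmark design: optima uniform on
#' `[0, 5]` log-expression units (the range of quantile-normalized
#' log-FPKM in the motivating *Drosophila* tissue data), selection strength
#' `alpha` log10-uniform on `[0, 3]`, drift variance `sigma2` log10-uniform
#' on `[-2, 3]`, and `m = 6` conditions.
#'
#' @param theta_range Closed interval for the optima, log-expression units.
#' @param alpha_range Closed interval for `alpha` on the natural scale.
#' @param sigma2_range Closed interval for `sigma2` on the natural scale.
#' @param alpha_sampling `"log"` (uniform in `log10(alpha)`) or `"linear"`
#'   (uniform in `alpha`).
#' @param sigma2_sampling As `alpha_sampling`, for `sigma2`.
#' @param m Number of conditions (tissues) measured per species.
#'
#' @return An object of class `"prior_spec"`.
#' @examples
#' prior_spec()                                  # benchmark default
#' prior_spec(alpha_sampling = "linear",
#'            sigma2_sampling = "linear")        # non-uniform variant
#' @export
prior_spec <- function(theta_range = c(0, 5),
                       alpha_range = c(1, 1000),
                       sigma2_range = c(0.01, 1000),
                       alpha_sampling = c("log", "linear"),
                       sigma2_sampling = c("log", "linear"),
                       m = 6L) {
  alpha_sampling <- match.arg(alpha_sampling)
  sigma2_sampling <- match.arg(sigma2_sampling)
  check_interval <- function(x, name, positive = FALSE) {
    if (length(x) != 2L || !all(is.finite(x)) || x[1] > x[2])
      stop(name, " must be an ordered finite interval")
    if (positive && x[1] <= 0)
      stop(name, " must be strictly positive")
  }
  check_interval(theta_range, "theta_range")
  check_interval(alpha_range, "alpha_range", positive = TRUE)
  check_interval(sigma2_range, "sigma2_range", positive = TRUE)
  m <- as.integer(m)
  stopifnot(m >= 1L)
  structure(list(theta_range = theta_range,
                 alpha_range = alpha_range,
                 sigma2_range = sigma2_range,
                 alpha_sampling = alpha_sampling,
                 sigma2_sampling = sigma2_sampling,
                 m = m),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Simulation prior (m = %d conditions)\n", x$m))
  cat(sprintf("  theta1, theta2 ~ U[%g, %g]\n",
              x$theta_range[1], x$theta_range[2]))
  cat(sprintf("  alpha  ~ %s-uniform on [%g, %g]\n",
              x$alpha_sampling, x$alpha_range[1], x$alpha_range[2]))
  cat(sprintf("  sigma2 ~ %s-uniform on [%g, %g]\n",
              x$sigma2_sampling, x$sigma2_range[1], x$sigma2_range[2]))
  invisible(x)
}

#' Restrict a prior to a rectangular (alpha, sigma2) regime
#'
#' Returns a copy of `base` in which `alpha` and `sigma2` are drawn
#' linear-uniformly inside the given restricted ranges, as in the
#' regime-specific test sets; the optima are untouched.
#'
#' @param alpha_range Restricted interval for `alpha` (within the base
#'   support).
#' @param sigma2_range Restricted interval for `sigma2`.
#' @param base The full [prior_spec()] being restricted.
#' @return A `"prior_spec"` object.
#' @examples
#' regime_prior(c(100, 1000), c(0.01, 0.1))  # strong selection, weak drift
#' @export
regime_prior <- function(alpha_range, sigma2_range, base = prior_spec()) {
  if (alpha_range[1] < base$alpha_range[1] ||
      alpha_range[2] > base$alpha_range[2])
    stop("alpha_range outside the base prior's support")
  if (sigma2_range[1] < base$sigma2_range[1] ||
      sigma2_range[2] > base$sigma2_range[2])
    stop("sigma2_range outside the base prior's support")
  prior_spec(theta_range = base$theta_range,
             alpha_range = alpha_range,
             sigma2_range = sigma2_range,
             alpha_sampling = "linear",
             sigma2_sampling = "linear",
             m = base$m)
}

draw_scaled <- function(n, range, sampling) {
  if (sampling == "log") {
    10^runif(n, log10(range[1]), log10(range[2]))
  } else {
    runif(n, range[1], range[2])
  }
}

class_levels <- c("conserved", "diverged")

#' Draw OU parameters for one condition given the class label
#'
#' For the `"conserved"` class the two optima are set exactly equal
#' (`theta2 := theta1`); for `"diverged"` they are drawn independently, so
#' they differ with probability one.
#'
#' @param prior A [prior_spec()].
#' @param label `"conserved"` or `"diverged"`.
#' @return An [ou_params()] object.
#' @export
draw_condition_params <- function(prior, label = c("conserved", "diverged")) {
  label <- match.arg(label)
  theta1 <- runif(1, prior$theta_range[1], prior$theta_range[2])
  theta2 <- if (label == "conserved") theta1 else
    runif(1, prior$theta_range[1], prior$theta_range[2])
  ou_params(theta1, theta2,
            alpha = draw_scaled(1, prior$alpha_range, prior$alpha_sampling),
            sigma2 = draw_scaled(1, prior$sigma2_range,
                                 prior$sigma2_sampling))
}

#' Simulate the feature vector of one ortholog pair
#'
#' Draws independent OU parameters for each of the `m` conditions
#' (conditioned on the class label) and one expression pair per condition.
#' Features are interleaved by condition:
#' `(e1_c1, e2_c1, ..., e1_cm, e2_cm)`.
#'
#' @inheritParams draw_condition_params
#' @return A list with `features` (length `2 * m` named numeric vector) and
#'   `params` (an `m` x 4 matrix of the true `theta1`, `theta2`, `alpha`,
#'   `sigma2` per condition).
#' @export
simulate_ortholog_pair <- function(prior,
                                   label = c("conserved", "diverged")) {
  label <- match.arg(label)
  m <- prior$m
  features <- numeric(2 * m)
  params <- matrix(NA_real_, m, 4,
                   dimnames = list(NULL,
                                   c("theta1", "theta2", "alpha", "sigma2")))
  for (k in seq_len(m)) {
    p <- draw_condition_params(prior, label)
    e <- ou_sample(p, 1L)
    features[2 * k - 1] <- e[1, "e1"]
    features[2 * k] <- e[1, "e2"]
    params[k, ] <- c(p$theta1, p$theta2, p$alpha, p$sigma2)
  }
  names(features) <- feature_names(m)
  list(features = features, params = params)
}

feature_names <- function(m) {
  as.vector(rbind(paste0("e1_c", seq_len(m)), paste0("e2_c", seq_len(m))))
}

param_names <- function(m) {
  as.vector(vapply(seq_len(m), function(k)
    paste0(c("theta1", "theta2", "alpha", "sigma2"), "_c", k),
    character(4)))
}

#' Simulate a labeled dataset of ortholog expression vectors
#'
#' Generates `n_conserved + n_diverged` ortholog pairs under `prior`, each
#' with independent per-condition OU parameters (so `4 * m` true parameter
#' values per pair), and shuffles the record order so classes are mixed for
#' mini-batch training.  The benchmark design uses 10,000 pairs per class
#' for training and 1,000 per class for testing.
#'
#' @param prior A [prior_spec()].
#' @param n_conserved,n_diverged Number of pairs simulated from each class.
#' @param seed Optional integer seed; when given, the dataset is a
#'   deterministic function of `(prior, counts, seed)`.
#' @return An object of class `"ortholog_data"`: a list with `features`
#'   (`N` x `2m` matrix), `labels` (factor with levels `"conserved"`,
#'   `"diverged"`), `params` (`N` x `4m` matrix of true parameters), and
#'   the generating `prior` and `seed`.
#' @examples
#' d <- simulate_dataset(prior_spec(), 50, 50, seed = 1)
#' table(d$labels)
#' @export
simulate_dataset <- function(prior, n_conserved, n_diverged, seed = NULL) {
  stopifnot(n_conserved >= 0, n_diverged >= 0)
  n <- n_conserved + n_diverged
  if (n == 0L) stop("cannot generate an empty dataset")
  if (!is.null(seed)) set.seed(seed)
  m <- prior$m

  labels <- factor(rep(class_levels, c(n_conserved, n_diverged)),
                   levels = class_levels)
  nm <- n * m
  theta1 <- matrix(runif(nm, prior$theta_range[1], prior$theta_range[2]),
                   n, m)
  theta2 <- matrix(runif(nm, prior$theta_range[1], prior$theta_range[2]),
                   n, m)
  conserved <- labels == "conserved"
  theta2[conserved, ] <- theta1[conserved, ]
  alpha <- matrix(draw_scaled(nm, prior$alpha_range, prior$alpha_sampling),
                  n, m)
  sigma2 <- matrix(draw_scaled(nm, prior$sigma2_range,
                               prior$sigma2_sampling), n, m)

  decay <- exp(-alpha)
  mu1 <- theta1
  mu2 <- (1 - decay) * theta2 + decay * theta1
  sd_stat <- sqrt(sigma2 / (2 * alpha))
  rho <- exp(-2 * alpha)
  z1 <- matrix(rnorm(nm), n, m)
  z2 <- matrix(rnorm(nm), n, m)
  e1 <- mu1 + sd_stat * z1
  e2 <- mu2 + sd_stat * (rho * z1 + sqrt(pmax(1 - rho^2, 0)) * z2)

  features <- matrix(NA_real_, n, 2 * m,
                     dimnames = list(NULL, feature_names(m)))
  features[, seq(1, 2 * m, by = 2)] <- e1
  features[, seq(2, 2 * m, by = 2)] <- e2
  params <- matrix(NA_real_, n, 4 * m,
                   dimnames = list(NULL, param_names(m)))
  params[, seq(1, 4 * m, by = 4)] <- theta1
  params[, seq(2, 4 * m, by = 4)] <- theta2
  params[, seq(3, 4 * m, by = 4)] <- alpha
  params[, seq(4, 4 * m, by = 4)] <- sigma2

  ord <- sample.int(n)
  structure(list(features = features[ord, , drop = FALSE],
                 labels = labels[ord],
                 params = params[ord, , drop = FALSE],
                 m = m, prior = prior, seed = seed,
                 n_conserved = n_conserved, n_diverged = n_diverged),
            class = "ortholog_data")
}

#' @export
print.ortholog_data <- function(x, ...) {
  cat(sprintf(
    "Simulated ortholog dataset: %d pairs (%d conserved, %d diverged), m = %d\n",
    nrow(x$features), sum(x$labels == "conserved"),
    sum(x$labels == "diverged"), x$m))
  invisible(x)
}

#' Write / read a simulated dataset as TSV
#'
#' The TSV holds one row per ortholog pair: `gene_id`, `label`, the `2m`
#' interleaved expression features, and the `4m` true parameters.  The
#' prior and seed are stored in `#`-prefixed header comments so a round
#' trip reconstructs the full object.
#'
#' @param data An `"ortholog_data"` object.
#' @param path File path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns an `"ortholog_data"` object.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "ortholog_data"))
  pr <- data$prior
  hdr <- c(
    sprintf("# m=%d", pr$m),
    sprintf("# theta_range=%.15g,%.15g", pr$theta_range[1], pr$theta_range[2]),
    sprintf("# alpha_range=%.15g,%.15g", pr$alpha_range[1], pr$alpha_range[2]),
    sprintf("# sigma2_range=%.15g,%.15g",
            pr$sigma2_range[1], pr$sigma2_range[2]),
    sprintf("# alpha_sampling=%s", pr$alpha_sampling),
    sprintf("# sigma2_sampling=%s", pr$sigma2_sampling),
    sprintf("# seed=%s", if (is.null(data$seed)) "NA" else data$seed))
  df <- data.frame(gene_id = sprintf("sim_%05d", seq_len(nrow(data$features))),
                   label = as.character(data$labels),
                   data$features, data$params, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  lines <- readLines(path, n = 20L)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s=", key), "",
                           grep(sprintf("^# %s=", key), hdr, value = TRUE))
  num2 <- function(key) as.numeric(strsplit(get(key), ",")[[1]])
  prior <- prior_spec(theta_range = num2("theta_range"),
                      alpha_range = num2("alpha_range"),
                      sigma2_range = num2("sigma2_range"),
                      alpha_sampling = get("alpha_sampling"),
                      sigma2_sampling = get("sigma2_sampling"),
                      m = as.integer(get("m")))
  seed <- get("seed")
  seed <- if (identical(seed, "NA")) NULL else as.integer(seed)
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  m <- prior$m
  features <- as.matrix(df[, feature_names(m), drop = FALSE])
  params <- as.matrix(df[, param_names(m), drop = FALSE])
  labels <- factor(df$label, levels = class_levels)
  structure(list(features = features, labels = labels, params = params,
                 m = m, prior = prior, seed = seed,
                 n_conserved = sum(labels == "conserved"),
                 n_diverged = sum(labels == "diverged")),
            class = "ortholog_data")
}

#' Simulate an empirical-style ortholog expression table
#'
#' Emulates the layout of a two-species tissue expression table (one row
#' per single-copy ortholog pair; per-species condition columns holding
#' log-scale, quantile-normalized values in roughly `[0, 5]`).  Useful for
#' exercising the empirical pipeline without external data.  The true
#' class of each gene is returned in the `true_label` column, which the
#' pipeline itself ignores.
#'
#' @param n_conserved,n_diverged Number of genes simulated from each class.
#' @param prior A [prior_spec()] controlling the generating process.
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `gene_id`, `sp1_c1..sp1_cm`,
#'   `sp2_c1..sp2_cm`, and `true_label`.
#' @export
simulate_ortholog_table <- function(n_conserved, n_diverged,
                                    prior = prior_spec(), seed = NULL) {
  d <- simulate_dataset(prior, n_conserved, n_diverged, seed = seed)
  m <- d$m
  sp1 <- d$features[, seq(1, 2 * m, by = 2), drop = FALSE]
  sp2 <- d$features[, seq(2, 2 * m, by = 2), drop = FALSE]
  colnames(sp1) <- paste0("sp1_c", seq_len(m))
  colnames(sp2) <- paste0("sp2_c", seq_len(m))
  data.frame(gene_id = sprintf("gene_%05d", seq_len(nrow(sp1))),
             sp1, sp2, true_label = as.character(d$labels),
             check.names = FALSE)
}
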