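#' Ornstein-Uhlenbeck parameters for one ortholog pair in one condition
#'
#' Bundles the four evolutionary parameters of the bivariate
#' Ornstein-Uhlenbeck (OU) model of ortholog expression: the expression
#' optima `theta1` (Species 1, carrying the ancestral optimum) and `theta2`
#' (Species 2, the species whose optimum may have shifted), the selection
#' strength `alpha`, and the drift variance `sigma2`.  Divergence time is
#' absorbed into `alpha` and `sigma2` (one time unit between the species),
#' so no branch length is exposed.
#'
#' @param theta1 Expression optimum of Species 1, log-expression units.
#' @param theta2 Expression optimum of Species 2, log-expression units.
#' @param alpha Selection strength, per unit divergence time. Must exceed
#'   `1e-12` to keep the stationary covariance non-singular.
#' @param sigma2 Drift variance rate, squared log-expression units per unit
#'   time. Must exceed `1e-12`.
#'
#' @return An object of class `"ou_params"`: a named list of the four
#'   parameters.
#' @examples
#' ou_params(theta1 = 2, theta2 = 4, alpha = 10, sigma2 = 0.5)
#' @export
ou_params <- function(theta1, theta2, alpha, sigma2) {
  stopifnot(length(theta1) == 1L, length(theta2) == 1L,
            length(alpha) == 1L, length(sigma2) == 1L)
  if (!is.finite(theta1) || !is.finite(theta2))
    stop("theta1 and theta2 must be finite")
  if (!is.finite(alpha) || alpha <= 1e-12)
    stop("alpha must be positive (> 1e-12)")
  if (!is.finite(sigma2) || sigma2 <= 1e-12)
    stop("sigma2 must be positive (> 1e-12)")
  structure(list(theta1 = theta1, theta2 = theta2,
                 alpha = alpha, sigma2 = sigma2),
            class = "ou_params")
}

#' @export
print.ou_params <- function(x, ...) {
  cat(sprintf(
    "OU parameters: theta1 = %g, theta2 = %g, alpha = %g, sigma2 = %g\n",
    x$theta1, x$theta2, x$alpha, x$sigma2))
  invisible(x)
}

as_ou_params <- function(params) {
  if (inherits(params, "ou_params")) return(params)
  ou_params(params[["theta1"]], params[["theta2"]],
            params[["alpha"]], params[["sigma2"]])
}

#' Expected log-expression of the two orthologs
#'
#' Closed-form mean of the bivariate OU model.  Species 1 retains the
#' ancestral optimum, so `E[e1] = theta1`; Species 2 relaxes from the
#' ancestral optimum toward its own, so
#' `E[e2] = (1 - exp(-alpha)) * theta2 + exp(-alpha) * theta1`.
#'
#' @param params An [ou_params()] object (or a named list/vector with the
#'   same fields).
#' @return Named numeric vector `c(e1 = ..., e2 = ...)`.
#' @examples
#' ou_mean(ou_params(0, 1, alpha = 1, sigma2 = 1))  # e2 = 1 - exp(-1)
#' @export
ou_mean <- function(params) {
  p <- as_ou_params(params)
  decay <- exp(-p$alpha)
  c(e1 = p$theta1, e2 = (1 - decay) * p$theta2 + decay * p$theta1)
}

#' Stationary covariance of the two orthologs' log-expression
#'
#' Both marginal variances equal `sigma2 / (2 * alpha)` and the
#' between-species covariance is `sigma2 / (2 * alpha) * exp(-2 * alpha)`,
#' giving correlation `exp(-2 * alpha)`.
#'
#' @inheritParams ou_mean
#' @return A symmetric 2x2 numeric matrix.
#' @examples
#' ou_covariance(ou_params(0, 0, alpha = 1, sigma2 = 2))
#' @export
ou_covariance <- function(params) {
  p <- as_ou_params(params)
  v <- p$sigma2 / (2 * p$alpha)
  cv <- v * exp(-2 * p$alpha)
  matrix(c(v, cv, cv, v), 2, 2,
         dimnames = list(c("e1", "e2"), c("e1", "e2")))
}

#' Sample ortholog expression pairs from the OU model
#'
#' Draws i.i.d. pairs from the bivariate normal distribution implied by
#' [ou_mean()] and [ou_covariance()].  Uses R's global RNG stream, so
#' `set.seed()` makes draws reproducible.
#'
#' @inheritParams ou_mean
#' @param n Number of pairs to draw.
#' @return An `n` x 2 matrix with columns `e1`, `e2`.
#' @examples
#' set.seed(1)
#' ou_sample(ou_params(1, 3, alpha = 5, sigma2 = 1), n = 4)
#' @export
ou_sample <- function(params, n = 1L) {
  stopifnot(n >= 1L)
  p <- as_ou_params(params)
  mu <- ou_mean(p)
  v <- p$sigma2 / (2 * p$alpha)
  rho <- exp(-2 * p$alpha)
  # Cholesky factor of v * [[1, rho], [rho, 1]]
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  sd <- sqrt(v)
  e1 <- mu[["e1"]] + sd * z1
  e2 <- mu[["e2"]] + sd * (rho * z1 + sqrt(max(1 - rho^2, 0)) * z2)
  cbind(e1 = e1, e2 = e2)
}

#' Log-density of an expression pair under the OU model
#'
#' Bivariate normal log-density at `e` with the closed-form OU moments.
#'
#' @param e Numeric vector `c(e1, e2)` (or a 2-column matrix of pairs).
#' @inheritParams ou_mean
#' @return Numeric log-density (one value per row of `e`).
#' @export
ou_log_density <- function(e, params) {
  p <- as_ou_params(params)
  if (is.null(dim(e))) e <- matrix(e, ncol = 2)
  stopifnot(ncol(e) == 2)
  mu <- ou_mean(p)
  v <- p$sigma2 / (2 * p$alpha)
  rho <- exp(-2 * p$alpha)
  det_sigma <- v^2 * (1 - rho^2)
  if (!is.finite(det_sigma) || det_sigma <= 0)
    stop("degenerate OU covariance: correlation numerically 1")
  d1 <- e[, 1] - mu[["e1"]]
  d2 <- e[, 2] - mu[["e2"]]
  quad <- (d1^2 - 2 * rho * d1 * d2 + d2^2) / (v * (1 - rho^2))
  -log(2 * pi) - 0.5 * log(det_sigma) - 0.5 * quad
}
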