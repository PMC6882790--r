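#' Sigmoidal response mapping
#'
#' Maps an internal confidence estimate c in \[0, 1\] onto a predicted report
#' through a logistic function of an odd polynomial of the standardized
#' estimate c' = 2(c - 0.5):
#' yhat = logistic(w0 + w1 c' + w2 c'^3).
#' With w0 = 0 the mapping is antisymmetric about 0.5, i.e. treats blue and
#' red majorities symmetrically; a nonzero intercept breaks that symmetry and
#' models a global response bias.
#'
#' @param c confidence estimate(s) in \[0, 1\].
#' @param w numeric length-3 weight vector \code{c(w0, w1, w2)}.
#' @return Predicted report(s) in (0, 1).
#' @export
sigmoid_map <- function(c, w) {
  if (any(c < 0 | c > 1)) stop("confidence must lie in [0, 1]")
  sigmoid_map_raw(2 * (c - 0.5), w)
}

## mapping on an already-standardized (or unbounded, e.g. count-difference)
## internal estimate x: logistic(w0 + w1 x + w2 x^3)
sigmoid_map_raw <- function(x, w) {
  stopifnot(length(w) == 3, all(is.finite(w)))
  stats::plogis(w[1] + w[2] * x + w[3] * x^3)
}

#' Polynomial terms of the flexible hierarchical response mapping
#'
#' Builds the nine-term design matrix in (q, N, M): with q' = 2(q - 0.5) and
#' M' = 2(M - 0.5), the terms are
#' \{1, q', q'N, M', q'^3, q'^3 N, N M', M'^3, N M'^3\}.
#' Only odd powers of q' and M' appear, so the non-intercept part is
#' antisymmetric under a joint red/blue relabeling; N enters raw as a
#' magnifier of the signed quantities.
#'
#' @param q sample proportion(s) in \[0, 1\].
#' @param N sample size(s).
#' @param M context estimate(s) in \[0, 1\].
#' @return Matrix with 9 columns, one row per trial.
#' @export
flexible_terms <- function(q, N, M) {
  qp <- 2 * (q - 0.5)
  Mp <- 2 * (M - 0.5)
  cbind(1, qp, qp * N, Mp, qp^3, qp^3 * N, N * Mp, Mp^3, N * Mp^3)
}

#' Per-term standardization scales for the flexible mapping
#'
#' Standard deviation of each non-constant polynomial term over a set of
#' (training) inputs; the intercept scale is fixed at 1, and any degenerate
#' (constant) term gets scale 1 so that division is harmless.
#'
#' @inheritParams flexible_terms
#' @return Numeric vector of 9 positive scales.
#' @export
flexible_term_scales <- function(q, N, M) {
  X <- flexible_terms(q, N, M)
  s <- unname(apply(X, 2, stats::sd))
  s[1] <- 1
  s[!is.finite(s) | s < 1e-12] <- 1
  s
}

#' Flexible hierarchical response mapping
#'
#' Weighted sum of the standardized polynomial terms passed through a
#' logistic: the function-approximator mapping \code{(q, N, M) -> yhat} used
#' to combine the current sample with any context estimate M (probabilistic
#' or heuristic) without committing to a particular integration rule.
#'
#' @inheritParams flexible_terms
#' @param w numeric length-9 weight vector.
#' @param term_scales length-9 positive divisors per term, typically
#'   [flexible_term_scales()] of the training inputs. Must be supplied.
#' @return Predicted report(s) in (0, 1).
#' @export
flexible_map <- function(q, N, M, w, term_scales) {
  stopifnot(length(w) == 9, all(is.finite(w)))
  if (missing(term_scales) || is.null(term_scales))
    stop("term_scales must be set (freeze them from the training inputs)")
  stopifnot(length(term_scales) == 9, all(term_scales > 0))
  if (any(q < 0 | q > 1) || any(M < 0 | M > 1))
    stop("q and M must lie in [0, 1]")
  X <- flexible_terms(q, N, M)
  Z <- sweep(X, 2, term_scales, "/") %*% w
  stats::plogis(drop(Z))
}

#' Log density of the \[0, 1\]-truncated Gaussian
#'
#' Density of Normal(y_hat, theta) renormalized to the unit interval; the
#' response-noise kernel of the report likelihood.
#'
#' @param y observed report(s) in \[0, 1\].
#' @param y_hat predicted report(s) in \[0, 1\].
#' @param theta positive SD of the underlying Gaussian.
#' @return Log density value(s).
#' @export
truncated_gauss_logpdf <- function(y, y_hat, theta) {
  if (any(theta <= 0)) stop("theta must be positive")
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]")
  Z <- stats::pnorm(1, y_hat, theta) - stats::pnorm(0, y_hat, theta)
  stats::dnorm(y, y_hat, theta, log = TRUE) - log(Z)
}

#' Mean of the truncated response distribution
#'
#' Expected report under \[0, 1\]-truncated Gaussian noise around the model
#' prediction: yhat + theta (phi(alpha) - phi(beta)) / (Phi(beta) -
#' Phi(alpha)) with alpha = -yhat/theta, beta = (1 - yhat)/theta. Truncation
#' pulls the expectation toward the center relative to the noiseless
#' prediction.
#'
#' @inheritParams truncated_gauss_logpdf
#' @return Expected report(s) in (0, 1).
#' @export
expected_response <- function(y_hat, theta) {
  a <- -y_hat / theta
  b <- (1 - y_hat) / theta
  y_hat + theta * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

#' Default lapse floor
#'
#' The constant added to the response likelihood so that far-outlying
#' reports keep non-vanishing probability: the standard-normal density at
#' four standard deviations, about 1.34e-4.
#'
#' @return Scalar lapse floor.
#' @export
default_epsilon <- function() stats::dnorm(4)

#' Response log-likelihood with lapse floor
#'
#' Sum over trials of log\[(1 - eps) TruncNormal(y | yhat, theta) + eps\]:
#' truncated-Gaussian response noise around the model prediction mixed with a
#' uniform lapse component of weight eps (the uniform density on \[0, 1\]
#' is 1, so the mixture density integrates to one).
#'
#' @param y observed reports in \[0, 1\].
#' @param y_hat model predictions in \[0, 1\] (same length).
#' @param theta truncated-Gaussian SD (> 0).
#' @param epsilon lapse floor, default [default_epsilon()].
#' @return Scalar total log-likelihood.
#' @export
response_loglik <- function(y, y_hat, theta, epsilon = default_epsilon()) {
  if (length(y_hat) != length(y) || any(!is.finite(y_hat)))
    stop("every response needs a finite model prediction")
  ll <- truncated_gauss_logpdf(y, y_hat, theta)
  sum(log((1 - epsilon) * exp(ll) + epsilon))
}

## Gaussian (untruncated) variant used by the conditional regression
## analyses: down-weights extreme responses by letting density spill over
## the unit interval.
gaussian_loglik <- function(y, y_hat, theta, epsilon = default_epsilon()) {
  sum(log((1 - epsilon) * stats::dnorm(y, y_hat, theta) + epsilon))
}
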