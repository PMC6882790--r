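#' Ideal-observer confidence for the flat (single-level) task
#'
#' Posterior confidence that the hidden proportion of blue items exceeds 1/2,
#' given a sample of \code{N_B} blue and \code{N_R} red items and a conjugate
#' Beta prior over the proportion. The posterior is Beta(\code{N_B + prior_a},
#' \code{N_R + prior_b}); confidence in a blue majority is its upper-tail mass
#' above 0.5, evaluated with the regularized incomplete Beta function.
#'
#' @param N_B,N_R non-negative integer counts of blue and red items (vectorized).
#' @param prior_a,prior_b positive shape parameters of the Beta prior over the
#'   hidden proportion. The task's flat condition uses Beta(4, 4).
#' @return A data.frame with columns \code{confidence_blue}, \code{posterior_a},
#'   \code{posterior_b}, one row per input trial.
#' @examples
#' exp1_confidence(4, 2)          # Beta(8,6) upper tail above 0.5
#' exp1_confidence(3, 3)$confidence_blue  # symmetric sample -> 0.5
#' @export
exp1_confidence <- function(N_B, N_R, prior_a = 4, prior_b = 4) {
  if (any(N_B < 0) || any(N_R < 0))
    stop("counts must be non-negative")
  if (prior_a <= 0 || prior_b <= 0)
    stop("prior shapes must be positive")
  a <- N_B + prior_a
  b <- N_R + prior_b
  data.frame(
    confidence_blue = stats::pbeta(0.5, a, b, lower.tail = FALSE),
    posterior_a = a,
    posterior_b = b
  )
}

## log Beta-binomial evidence of a sample under context b, up to the
## binomial coefficient (common to both contexts, cancels on normalization):
## log B(N_B + a, N_R + c) - log B(a, c)
log_bb_evidence <- function(N_B, N_R, shape1, shape2) {
  lbeta(N_B + shape1, N_R + shape2) - lbeta(shape1, shape2)
}

#' Bottom-up context message from a single trial
#'
#' The normalized per-trial likelihood of the binary block tendency after
#' integrating out the trial's hidden proportion: m(b) is proportional to the
#' Beta-binomial marginal of the observed counts under the Beta(nu1, nu2)
#' (blue tendency, b = 1) or Beta(nu2, nu1) (red tendency, b = 0) component.
#' Evaluated in log space via \code{lbeta}.
#'
#' @param N_B,N_R observed counts.
#' @param nu1,nu2 positive Beta shapes of the skewed tendency distribution,
#'   convention \code{nu1 >= nu2} meaning the b = 1 component favors blue.
#' @return Numeric vector of length 2: \code{c(m0, m1)}, probabilities of
#'   b = 0 and b = 1, summing to one.
#' @export
trial_message <- function(N_B, N_R, nu1 = 14, nu2 = 9) {
  if (!is.finite(nu1) || !is.finite(nu2) || nu1 <= 0 || nu2 <= 0)
    stop("tendency shapes must be finite and positive")
  if (N_B < 0 || N_R < 0) stop("counts must be non-negative")
  l1 <- log_bb_evidence(N_B, N_R, nu1, nu2)
  l0 <- log_bb_evidence(N_B, N_R, nu2, nu1)
  z <- max(l0, l1)
  w <- exp(c(l0, l1) - z)
  w / sum(w)
}

#' Accumulated belief about the block tendency
#'
#' Pointwise product of the context prior and all previous-trial messages,
#' renormalized. With no messages the prior is returned unchanged.
#'
#' @param messages list of length-2 probability vectors \code{c(m0, m1)}
#'   (may be empty).
#' @param prior_b prior probability of a blue tendency (b = 1), default 0.5.
#' @return Length-2 probability vector \code{c(M0, M1)}.
#' @export
update_context_belief <- function(messages = list(), prior_b = 0.5) {
  if (prior_b < 0 || prior_b > 1) stop("prior_b must be a probability")
  logM <- log(c(1 - prior_b, prior_b))
  for (m in messages) {
    if (length(m) != 2 || any(!is.finite(m)) || any(m < 0) || any(m > 1))
      stop("each message must be a probability pair")
    logM <- logM + log(m)
  }
  w <- exp(logM - max(logM))
  w / sum(w)
}

#' Hierarchical ideal-observer confidence for the blocked task
#'
#' Confidence that the current trial's hidden proportion exceeds 1/2, mixing
#' the two context-conditional posteriors by the current belief about the
#' block tendency. Each context term is the Beta-binomial evidence of the
#' current sample times the upper-tail mass of the context-conditional Beta
#' posterior, normalized over contexts.
#'
#' @param N_B,N_R current-trial counts.
#' @param belief length-2 probability vector \code{c(M0, M1)}, the belief
#'   about the tendency computed from previous trials
#'   (see [update_context_belief()]).
#' @param nu1,nu2 tendency Beta shapes.
#' @return Scalar confidence in a blue majority, in \[0, 1\].
#' @export
exp2_confidence <- function(N_B, N_R, belief = c(0.5, 0.5), nu1 = 14, nu2 = 9) {
  if (length(belief) != 2 || any(belief < 0) ||
      abs(sum(belief) - 1) > 1e-8)
    stop("belief must be a normalized probability pair")
  l1 <- log_bb_evidence(N_B, N_R, nu1, nu2)
  l0 <- log_bb_evidence(N_B, N_R, nu2, nu1)
  up1 <- stats::pbeta(0.5, N_B + nu1, N_R + nu2, lower.tail = FALSE)
  up0 <- stats::pbeta(0.5, N_B + nu2, N_R + nu1, lower.tail = FALSE)
  z <- max(l0, l1)
  e0 <- belief[1] * exp(l0 - z)
  e1 <- belief[2] * exp(l1 - z)
  (e0 * up0 + e1 * up1) / (e0 + e1)
}

#' Brute-force grid oracle for the hierarchical confidence
#'
#' Evaluates the joint posterior of a block prefix directly: for each context
#' it integrates every trial's binomial likelihood against the
#' context-conditional Beta density on a fine proportion grid (composite
#' trapezoid), forms the joint evidence, and normalizes. Intended as an
#' independent numerical check of [exp2_confidence()]; quadratic in nothing
#' but slow by design.
#'
#' @param N_B,N_R integer vectors over the block prefix; the last element is
#'   the current trial.
#' @param nu1,nu2 tendency Beta shapes.
#' @param prior_b prior probability of b = 1.
#' @param n_grid number of grid points for the proportion integrals.
#' @return Scalar confidence in a blue majority on the current trial.
#' @export
exp2_confidence_numeric <- function(N_B, N_R, nu1 = 14, nu2 = 9,
                                    prior_b = 0.5, n_grid = 1e5) {
  stopifnot(length(N_B) == length(N_R), length(N_B) >= 1)
  mu <- seq(0, 1, length.out = n_grid)
  trapz <- function(f) sum((f[-1] + f[-length(f)]) / 2) * (mu[2] - mu[1])
  upper <- mu >= 0.5
  Tn <- length(N_B)
  joint <- c(0, 0)      # per-context evidence of all trials, current truncated
  full <- c(0, 0)       # same, current integrated over [0,1]
  for (bi in 1:2) {
    b <- bi - 1
    a1 <- if (b == 1) nu1 else nu2
    a2 <- if (b == 1) nu2 else nu1
    dens <- stats::dbeta(mu, a1, a2)
    ev <- 1
    if (Tn > 1) {
      for (t in seq_len(Tn - 1)) {
        lik <- stats::dbinom(N_B[t], N_B[t] + N_R[t], mu)
        ev <- ev * trapz(lik * dens)
      }
    }
    lik_cur <- stats::dbinom(N_B[Tn], N_B[Tn] + N_R[Tn], mu) * dens
    p_b <- if (b == 1) prior_b else 1 - prior_b
    joint[bi] <- p_b * ev * trapz(lik_cur * as.numeric(upper))
    full[bi] <- p_b * ev * trapz(lik_cur)
  }
  sum(joint) / sum(full)
}

#' Batch ideal-observer pass over a trial table
#'
#' Vectorized message passing over a whole dataset: per-trial bottom-up
#' messages, the running belief about the block tendency from previous trials
#' in the same block (reset to the prior at block boundaries), and the
#' hierarchical confidence for every trial.
#'
#' @param trials data.frame with columns \code{block_id}, \code{t}
#'   (within-block position), \code{N_B}, \code{N_R}. Rows must be ordered by
#'   block and position.
#' @param nu1,nu2 tendency Beta shapes.
#' @param prior_b prior probability of a blue tendency.
#' @return \code{trials} with added columns \code{m1} (message for b = 1 from
#'   this trial), \code{M1} (belief in b = 1 from strictly previous in-block
#'   trials), and \code{confidence} (hierarchical confidence in a blue
#'   majority).
#' @export
exp2_observer_batch <- function(trials, nu1 = 14, nu2 = 9, prior_b = 0.5) {
  stopifnot(all(c("block_id", "t", "N_B", "N_R") %in% names(trials)))
  l1 <- log_bb_evidence(trials$N_B, trials$N_R, nu1, nu2)
  l0 <- log_bb_evidence(trials$N_B, trials$N_R, nu2, nu1)
  lam <- l1 - l0                                   # per-trial log odds for b=1
  ## running within-block cumulative log odds of strictly previous trials
  cum <- stats::ave(lam, trials$block_id, FUN = function(x)
    c(0, cumsum(x)[-length(x)]))
  L <- log(prior_b / (1 - prior_b)) + cum
  M1 <- stats::plogis(L)
  up1 <- stats::pbeta(0.5, trials$N_B + nu1, trials$N_R + nu2,
                      lower.tail = FALSE)
  up0 <- stats::pbeta(0.5, trials$N_B + nu2, trials$N_R + nu1,
                      lower.tail = FALSE)
  z <- pmax(l0, l1)
  e0 <- (1 - M1) * exp(l0 - z)
  e1 <- M1 * exp(l1 - z)
  trials$m1 <- stats::plogis(lam)
  trials$M1 <- M1
  trials$confidence <- (e0 * up0 + e1 * up1) / (e0 + e1)
  trials
}

#' Batch single-level observer over a trial table
#'
#' Applies [exp1_confidence()] row-wise, returning the table with a
#' \code{confidence} column. Same batch contract as [exp2_observer_batch()]
#' so that fitting and analyses can treat observers polymorphically.
#'
#' @inheritParams exp1_confidence
#' @param trials data.frame with columns \code{N_B}, \code{N_R}.
#' @return \code{trials} with a \code{confidence} column added.
#' @export
exp1_observer_batch <- function(trials, prior_a = 4, prior_b = 4) {
  trials$confidence <- exp1_confidence(trials$N_B, trials$N_R,
                                       prior_a, prior_b)$confidence_blue
  trials
}
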