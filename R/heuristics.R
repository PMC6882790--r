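#' Ratio heuristic for the flat task
#'
#' The internal estimate is simply the sample proportion of blue items,
#' ignoring sample size. The downstream response mapping (see
#' [sigmoid_map()]) turns it into a predicted report.
#'
#' @param N_B,N_R counts (vectorized); \code{N_B + N_R >= 1}.
#' @return Sample proportion \code{N_B / (N_B + N_R)}.
#' @export
ratio_estimate <- function(N_B, N_R) {
  if (any(N_B + N_R < 1)) stop("empty sample")
  N_B / (N_B + N_R)
}

#' Difference heuristic for the flat task
#'
#' The internal estimate is the signed count difference \code{N_B - N_R},
#' which covaries with sample size but not through the posterior width.
#'
#' @param N_B,N_R counts (vectorized).
#' @return Integer difference \code{N_B - N_R}.
#' @export
difference_estimate_exp1 <- function(N_B, N_R) {
  N_B - N_R
}

#' Averaging heuristic for the block tendency
#'
#' Estimates the probability of a blue tendency as the plain mean of the
#' sample proportions of previous in-block trials, neglecting their sample
#' sizes. Indifference (0.5) on the first trial of a block.
#'
#' @param previous_q numeric vector of previous-trial sample proportions
#'   (may be empty).
#' @return Scalar estimate in \[0, 1\].
#' @export
averaging_context <- function(previous_q) {
  if (length(previous_q) == 0) return(0.5)
  if (any(previous_q < 0) || any(previous_q > 1))
    stop("proportions must lie in [0, 1]")
  mean(previous_q)
}

#' Tally heuristic for the block tendency
#'
#' Pools all previous in-block samples as if drawn from one population:
#' total blue count over total count. Larger previous samples therefore weigh
#' more, unlike the averaging heuristic.
#'
#' @param previous_N_B,previous_N integer vectors of previous-trial blue
#'   counts and sample sizes (may be empty).
#' @return Scalar estimate in \[0, 1\]; 0.5 with no previous trials.
#' @export
tally_context <- function(previous_N_B, previous_N) {
  stopifnot(length(previous_N_B) == length(previous_N))
  if (length(previous_N) == 0) return(0.5)
  if (any(previous_N < 1) || any(previous_N_B > previous_N) ||
      any(previous_N_B < 0))
    stop("invalid counts")
  sum(previous_N_B) / sum(previous_N)
}

#' Count-difference heuristic for the block tendency
#'
#' A logistic function of the running mean of previous-trial count
#' differences d = N_B - N_R, with sensitivity \code{omega}.
#'
#' @param previous_d integer vector of previous-trial count differences
#'   (may be empty).
#' @param omega sensitivity parameter.
#' @return Scalar estimate in (0, 1); 0.5 with no previous trials.
#' @export
difference_context <- function(previous_d, omega = 1) {
  if (length(previous_d) == 0) return(0.5)
  stats::plogis(omega * mean(previous_d))
}

#' Batch heuristic context estimates over a trial table
#'
#' Computes, for every trial, the chosen heuristic's estimate that the block
#' tendency is blue from the strictly previous trials of the same block.
#' Same batch contract as [exp2_observer_batch()].
#'
#' @param trials data.frame with columns \code{block_id}, \code{t},
#'   \code{N_B}, \code{N_R}, ordered by block and position.
#' @param model one of \code{"averaging"}, \code{"tally"},
#'   \code{"difference"}.
#' @param omega sensitivity of the difference heuristic (ignored otherwise).
#' @return \code{trials} with an \code{M1} column (estimate of a blue
#'   tendency before the current trial).
#' @export
heuristic_context_batch <- function(trials, model = c("averaging", "tally",
                                                      "difference"),
                                    omega = 1) {
  model <- match.arg(model)
  N <- trials$N_B + trials$N_R
  prev_cum <- function(x) stats::ave(x, trials$block_id, FUN = function(v)
    c(0, cumsum(v)[-length(v)]))
  n_prev <- stats::ave(rep(1, nrow(trials)), trials$block_id,
                       FUN = function(v) seq_along(v) - 1)
  M1 <- switch(model,
    averaging = {
      s <- prev_cum(trials$N_B / N)
      ifelse(n_prev == 0, 0.5, s / pmax(n_prev, 1))
    },
    tally = {
      sb <- prev_cum(trials$N_B)
      sn <- prev_cum(N)
      ifelse(n_prev == 0, 0.5, sb / pmax(sn, 1))
    },
    difference = {
      sd_ <- prev_cum(trials$N_B - trials$N_R)
      ifelse(n_prev == 0, 0.5,
             stats::plogis(omega * sd_ / pmax(n_prev, 1)))
    })
  trials$M1 <- M1
  trials
}
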