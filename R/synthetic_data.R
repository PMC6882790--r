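#' Generative configuration for the airplane task
#'
#' Bundles the parameters of the two-level generative process. The flat
#' condition (experiment 1) draws each trial's hidden blue proportion from
#' Beta(\code{prior_a}, \code{prior_b}) independently; the blocked condition
#' (experiment 2) first draws a binary block tendency b ~ Bernoulli(0.5) per
#' 5-trial block and then draws proportions from Beta(nu1, nu2) (b = 1, blue
#' tendency) or Beta(nu2, nu1) (b = 0). Sample sizes are uniform over
#' \code{sample_sizes}; observed blue counts are Binomial(N, mu).
#'
#' @param experiment \code{"exp1"} or \code{"exp2"}.
#' @param nu1,nu2 tendency Beta shapes, \code{nu1 >= nu2 > 0}; defaults 14, 9.
#' @param prior_a,prior_b flat-condition Beta prior shapes; defaults 4, 4.
#' @param sample_sizes positive integer set of sample sizes; defaults
#'   \{3, 5, ..., 13\} (exp1) or \{3, ..., 11\} (exp2).
#' @param trials_per_block trials per block in the blocked condition (5).
#' @return A list of class \code{"generative_config"}.
#' @export
generative_config <- function(experiment = c("exp1", "exp2"),
                              nu1 = 14, nu2 = 9,
                              prior_a = 4, prior_b = 4,
                              sample_sizes = NULL,
                              trials_per_block = 5) {
  experiment <- match.arg(experiment)
  if (is.null(sample_sizes))
    sample_sizes <- if (experiment == "exp1") seq(3, 13, by = 2) else 3:11
  if (length(sample_sizes) == 0 || any(sample_sizes < 1))
    stop("sample_sizes must be a nonempty set of positive integers")
  if (!(nu1 >= nu2 && nu2 > 0))
    stop("tendency shapes must satisfy nu1 >= nu2 > 0")
  if (prior_a <= 0 || prior_b <= 0) stop("prior shapes must be positive")
  structure(list(experiment = experiment, nu1 = nu1, nu2 = nu2,
                 prior_a = prior_a, prior_b = prior_b,
                 sample_sizes = as.integer(sample_sizes),
                 trials_per_block = as.integer(trials_per_block)),
            class = "generative_config")
}

## uniform categorical draw that is safe for singleton size sets
draw_sizes <- function(sizes, n) {
  sizes[sample.int(length(sizes), n, replace = TRUE)]
}

## finalize a trial table: counts, size, exact sample proportion
finish_trials <- function(df) {
  df$N <- df$N_B + df$N_R
  df$q <- df$N_B / df$N
  df
}

#' Simulate a flat-condition session
#'
#' Each trial independently: mu ~ Beta(prior_a, prior_b), N uniform on the
#' configured size set, N_B ~ Binomial(N, mu). The hidden proportion is kept
#' in the table (simulation-only truth).
#'
#' @param config a [generative_config()] with \code{experiment = "exp1"}.
#' @param n_trials number of trials (the study session used 280).
#' @param seed integer seed; fixed seed gives identical output.
#' @param mu_force optional fixed value for every trial's hidden proportion;
#'   a degenerate hook for unit tests, off by default.
#' @return data.frame with columns \code{session, block_id, t, mu_true, N_B,
#'   N_R, N, q} (one "block" per trial in the flat condition).
#' @export
sample_exp1_session <- function(config = generative_config("exp1"),
                                n_trials = 280, seed = 1, mu_force = NULL) {
  stopifnot(inherits(config, "generative_config"))
  if (config$experiment != "exp1") stop("config is not for the flat condition")
  if (n_trials < 1) stop("n_trials must be positive")
  set.seed(seed)
  mu <- if (is.null(mu_force))
    stats::rbeta(n_trials, config$prior_a, config$prior_b)
  else rep(mu_force, n_trials)
  N <- draw_sizes(config$sample_sizes, n_trials)
  N_B <- stats::rbinom(n_trials, N, mu)
  finish_trials(data.frame(session = 1L, block_id = seq_len(n_trials),
                           t = 1L, b = NA_integer_, mu_true = mu,
                           N_B = N_B, N_R = N - N_B))
}

#' Simulate blocked-condition sessions
#'
#' Per block: b ~ Bernoulli(0.5); per trial within the block: mu from the
#' b-conditional skewed Beta, N uniform on the size set, N_B ~ Binomial(N,
#' mu). Blocks are statistically independent. Each block consumes its own
#' child random stream (block seeds are drawn upfront from a master
#' generator), so extending \code{n_blocks} leaves earlier blocks unchanged.
#'
#' @param config a [generative_config()] with \code{experiment = "exp2"}.
#' @param n_blocks number of 5-trial blocks (the study's two sessions used
#'   54 + 60 = 114 blocks, i.e. 570 trials).
#' @param seed integer master seed.
#' @param mu_force optional fixed hidden proportion (test hook).
#' @return data.frame with columns \code{session, block_id, t, b, mu_true,
#'   N_B, N_R, N, q}.
#' @export
sample_exp2_session <- function(config = generative_config("exp2"),
                                n_blocks = 114, seed = 1, mu_force = NULL) {
  stopifnot(inherits(config, "generative_config"))
  if (config$experiment != "exp2")
    stop("config is not for the blocked condition")
  if (n_blocks < 1) stop("n_blocks must be positive")
  k <- config$trials_per_block
  set.seed(seed)
  block_seeds <- sample.int(.Machine$integer.max - 1, n_blocks)
  one_block <- function(i) {
    set.seed(block_seeds[i])
    b <- stats::rbinom(1, 1, 0.5)
    a1 <- if (b == 1) config$nu1 else config$nu2
    a2 <- if (b == 1) config$nu2 else config$nu1
    mu <- if (is.null(mu_force)) stats::rbeta(k, a1, a2) else rep(mu_force, k)
    N <- draw_sizes(config$sample_sizes, k)
    N_B <- stats::rbinom(k, N, mu)
    data.frame(session = 2L, block_id = i, t = seq_len(k), b = b,
               mu_true = mu, N_B = N_B, N_R = N - N_B)
  }
  finish_trials(do.call(rbind, lapply(seq_len(n_blocks), one_block)))
}

#' Specification of a simulated response agent
#'
#' Describes which internal observer produces the confidence estimate, how
#' the estimate is mapped onto the report scale, and the response noise.
#' Mappings: \code{"identity"} reports the estimate itself (valid only for
#' estimates already in \[0, 1\]); \code{"sigmoid"} applies [sigmoid_map()]
#' with \code{weights} of length 3; \code{"flexible"} applies
#' [flexible_map()] to (q, N, M) with \code{weights} of length 9 and unit
#' term scales unless \code{term_scales} is given.
#'
#' @param model one of \code{"ideal"} (posterior observer; hierarchical when
#'   the trials carry blocks), \code{"ratio"}, \code{"difference_exp1"},
#'   \code{"averaging"}, \code{"tally"}, \code{"difference_ctx"},
#'   \code{"mismatched_ideal"} (hierarchical observer run at
#'   \code{nu1p, nu2p} instead of the true shapes).
#' @param mapping response mapping, see Details.
#' @param weights mapping weight vector (ignored for \code{"identity"}).
#' @param theta truncated-Gaussian response SD, at least 0.01.
#' @param epsilon lapse probability in \[0, 0.01\]; with probability
#'   \code{epsilon} the report is uniform on \[0, 1\].
#' @param omega sensitivity of the count-difference context heuristic.
#' @param nu1p,nu2p subjective tendency shapes of the mismatched observer.
#' @param term_scales optional length-9 scales for the flexible mapping.
#' @return A list of class \code{"agent_spec"}.
#' @export
agent_spec <- function(model = "ideal",
                       mapping = c("identity", "sigmoid", "flexible"),
                       weights = NULL, theta = 0.1,
                       epsilon = default_epsilon(), omega = 1,
                       nu1p = 14, nu2p = 9, term_scales = NULL) {
  mapping <- match.arg(mapping)
  models <- c("ideal", "ratio", "difference_exp1", "averaging", "tally",
              "difference_ctx", "mismatched_ideal")
  if (!model %in% models) stop("unknown agent model: ", model)
  if (theta < 0.01) stop("theta must be at least 0.01")
  if (epsilon < 0 || epsilon > 0.01) stop("epsilon must lie in [0, 0.01]")
  if (mapping == "sigmoid" && (is.null(weights) || length(weights) != 3))
    stop("sigmoid mapping needs 3 weights")
  if (mapping == "flexible" && (is.null(weights) || length(weights) != 9))
    stop("flexible mapping needs 9 weights")
  structure(list(model = model, mapping = mapping, weights = weights,
                 theta = theta, epsilon = epsilon, omega = omega,
                 nu1p = nu1p, nu2p = nu2p, term_scales = term_scales),
            class = "agent_spec")
}

## noiseless predicted report of an agent on a trial table
agent_predictions <- function(trials, agent, config) {
  est <- switch(agent$model,
    ideal = if (all(is.na(trials$b)))
      exp1_observer_batch(trials, config$prior_a, config$prior_b)$confidence
    else
      exp2_observer_batch(trials, config$nu1, config$nu2)$confidence,
    mismatched_ideal =
      exp2_observer_batch(trials, agent$nu1p, agent$nu2p)$confidence,
    ratio = ratio_estimate(trials$N_B, trials$N_R),
    difference_exp1 = difference_estimate_exp1(trials$N_B, trials$N_R),
    averaging = ,
    tally = ,
    difference_ctx = {
      hm <- switch(agent$model, averaging = "averaging", tally = "tally",
                   difference_ctx = "difference")
      heuristic_context_batch(trials, hm, omega = agent$omega)$M1
    })
  switch(agent$mapping,
    identity = {
      if (agent$model %in% c("difference_exp1"))
        stop("identity mapping undefined for an unbounded estimate")
      if (agent$model %in% c("averaging", "tally", "difference_ctx"))
        stop("context heuristics need the flexible mapping")
      est
    },
    sigmoid = {
      x <- if (agent$model == "difference_exp1") est else 2 * (est - 0.5)
      sigmoid_map_raw(x, agent$weights)
    },
    flexible = {
      M <- if (agent$model %in% c("averaging", "tally", "difference_ctx"))
        est
      else if (agent$model %in% c("ideal", "mismatched_ideal"))
        exp2_observer_batch(trials,
                            if (agent$model == "ideal") config$nu1 else agent$nu1p,
                            if (agent$model == "ideal") config$nu2 else agent$nu2p)$M1
      else stop("flexible mapping needs a context estimate")
      sc <- if (is.null(agent$term_scales)) rep(1, 9) else agent$term_scales
      flexible_map(trials$q, trials$N, M, agent$weights, sc)
    })
}

## draws from the [0,1]-truncated Gaussian by inverse-CDF
rtruncgauss01 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Simulate agent confidence reports
#'
#' Computes the agent's noiseless predicted report for every trial, then
#' draws the report from the \[0, 1\]-truncated Gaussian around it with SD
#' \code{theta}; with probability \code{epsilon} the report is replaced by a
#' uniform draw (the generative counterpart of the lapse floor in the fitted
#' likelihood).
#'
#' @param trials a trial table from [sample_exp1_session()] or
#'   [sample_exp2_session()].
#' @param agent an [agent_spec()].
#' @param seed integer seed.
#' @param config the [generative_config()] the trials were drawn from
#'   (supplies the observer's prior / tendency shapes).
#' @return \code{trials} with columns \code{y_hat} (noiseless prediction)
#'   and \code{y} (noisy report) added.
#' @export
simulate_agent_responses <- function(trials, agent, seed = 1,
                                     config = NULL) {
  stopifnot(inherits(agent, "agent_spec"))
  if (is.null(config))
    config <- generative_config(if (all(is.na(trials$b))) "exp1" else "exp2")
  y_hat <- agent_predictions(trials, agent, config)
  set.seed(seed)
  n <- nrow(trials)
  y <- rtruncgauss01(n, y_hat, agent$theta)
  lapse <- stats::runif(n) < agent$epsilon
  y[lapse] <- stats::runif(sum(lapse))
  trials$y_hat <- y_hat
  trials$y <- pmin(pmax(y, 0), 1)
  trials
}

#' Score of a confidence report
#'
#' S = 1 - |y - y_opt|: proximity of the report to the optimal confidence.
#'
#' @param y report in \[0, 1\].
#' @param y_opt optimal report in \[0, 1\].
#' @return Score in \[0, 1\] (vectorized).
#' @export
score_response <- function(y, y_opt) {
  if (any(y < 0 | y > 1) || any(y_opt < 0 | y_opt > 1))
    stop("scores are defined on [0, 1] only")
  1 - abs(y - y_opt)
}
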