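#' Align a quantity to the block tendency
#'
#' Re-expresses a proportion-like quantity relative to the true block
#' tendency: x when the block favors blue (b = 1), 1 - x when it favors red
#' (b = 0). An involution: applying it twice restores x. Aligned quantities
#' pool the two symmetric contexts.
#'
#' @param x value(s) in \[0, 1\].
#' @param b binary block tendency label(s).
#' @return Aligned value(s).
#' @export
align_to_block <- function(x, b) {
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]")
  if (!all(b %in% c(0, 1))) stop("b must be binary")
  b * x + (1 - b) * (1 - x)
}

## logistic regression under the Gaussian-response likelihood of the
## conditional analyses: yhat = logistic(X w), y ~ (1-eps) N(yhat, theta) + eps
gauss_logistic_fit <- function(X, y, epsilon = default_epsilon()) {
  X <- as.matrix(X)
  p <- ncol(X)
  nll <- function(par)
    -gaussian_loglik(y, stats::plogis(drop(X %*% par[seq_len(p)])),
                     par[p + 1], epsilon)
  ## logit-scale least squares gives a start in the right basin; a neutral
  ## start guards against it failing on degenerate designs
  z <- stats::qlogis(pmin(pmax(y, 0.01), 0.99))
  w0 <- tryCatch(qr.solve(X, z), error = function(e) rep(0, p))
  if (any(!is.finite(w0))) w0 <- rep(0, p)
  th0 <- min(max(stats::sd(y - stats::plogis(drop(X %*% w0))), 0.011), 0.99)
  best <- NULL
  for (s0 in list(c(w0, th0), c(rep(0, p), 0.25))) {
    opt <- stats::optim(s0, nll, method = "L-BFGS-B",
                        lower = c(rep(-50, p), 0.01),
                        upper = c(rep(50, p), 1),
                        control = list(maxit = 500))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  list(weights = best$par[seq_len(p)], theta = best$par[p + 1],
       loglik = -best$value, converged = best$convergence == 0)
}

#' Confidence-curve slope conditional on sample size
#'
#' For trials of one sample size N, fits yhat = logistic(omega_N q') with
#' q' = 2(q - 0.5) by maximizing the lapse-mixture likelihood with an
#' untruncated Gaussian response kernel (which down-weights extreme reports
#' and stabilizes the slope under scarce conditioning).
#'
#' @param trials trial table with columns \code{q}, \code{N}, \code{y}.
#' @param sample_size the sample size N to condition on.
#' @param min_n minimum number of qualifying trials (default 20).
#' @return List with \code{weights} (named \code{omega}), nuisance
#'   \code{theta}, and \code{n}.
#' @export
slope_by_sample_size <- function(trials, sample_size, min_n = 20) {
  rows <- trials$N == sample_size
  if (sum(rows) < min_n)
    stop("need at least ", min_n, " trials at N = ", sample_size)
  fit <- gauss_logistic_fit(2 * (trials$q[rows] - 0.5), trials$y[rows])
  list(weights = c(omega = fit$weights), theta = fit$theta, n = sum(rows))
}

#' Regression weights of previous in-block trials
#'
#' For blocks observed up to position \code{T}, regresses the aligned report
#' at position T on the standardized aligned sample proportions of positions
#' 1..T-1: yhat = logistic(sum_t omega_t q_t'), fitted with the
#' Gaussian-response likelihood. Under hierarchical evidence accumulation the
#' weights should be equal on average across blocks.
#'
#' @param trials blocked trial table with columns \code{block_id}, \code{t},
#'   \code{q}, \code{y}, \code{b} (true tendency).
#' @param T current position, 3..5.
#' @param min_blocks minimum number of qualifying blocks.
#' @return List with \code{weights} (omega_1..omega_\{T-1\}), \code{theta},
#'   \code{n_blocks}.
#' @export
previous_trial_weights <- function(trials, T = 5, min_blocks = 20) {
  if (!T %in% 3:5) stop("T must be 3, 4 or 5")
  cur <- trials[trials$t == T, ]
  if (nrow(cur) < min_blocks) stop("too few blocks with position ", T)
  prev <- trials[trials$t < T, ]
  prev <- prev[order(prev$block_id, prev$t), ]
  cur <- cur[order(cur$block_id), ]
  keep <- cur$block_id %in% prev$block_id
  cur <- cur[keep, ]
  q_al <- align_to_block(prev$q, prev$b)
  Xw <- matrix(2 * (q_al - 0.5), ncol = T - 1, byrow = TRUE)
  y_al <- align_to_block(cur$y, cur$b)
  fit <- gauss_logistic_fit(Xw, y_al)
  list(weights = stats::setNames(fit$weights, paste0("omega_", seq_len(T - 1))),
       theta = fit$theta, n_blocks = nrow(cur))
}

#' Rate of evidence-opposing confidence reports
#'
#' Among trials whose aligned sample proportion falls strictly below one
#' half (current evidence opposes the block tendency), the fraction of
#' reports whose aligned confidence nevertheless exceeds one half. Also
#' simulates the same rate for a context-blind reference agent that reports
#' the aligned sample proportion plus truncated-Gaussian noise of SD 0.1,
#' whose opposing choices stem from response noise alone.
#'
#' @param trials blocked trial table with \code{q}, \code{y}, \code{b}.
#' @param theta_ref SD of the reference agent's response noise.
#' @param seed seed for the reference simulation.
#' @param n_sim total reference draws (spread over qualifying trials).
#' @return List with \code{rate}, \code{reference_rate}, \code{n_trials}.
#' @export
evidence_opposing_rate <- function(trials, theta_ref = 0.1, seed = 1,
                                   n_sim = 1e5) {
  q_al <- align_to_block(trials$q, trials$b)
  keep <- q_al < 0.5
  if (!any(keep)) stop("no trials with opposing sample evidence")
  y_al <- align_to_block(trials$y[keep], trials$b[keep])
  qk <- q_al[keep]
  set.seed(seed)
  reps <- max(1, ceiling(n_sim / length(qk)))
  y_ref <- rtruncgauss01(length(qk) * reps, rep(qk, reps), theta_ref)
  list(rate = mean(y_al > 0.5),
       reference_rate = mean(y_ref > 0.5),
       n_trials = sum(keep))
}

#' Equal-count binning of paired data
#'
#' Groups x into approximately equally filled quantile bins and returns
#' per-bin means and standard errors of y; a visualization device, analyses
#' run on the ungrouped data.
#'
#' @param x,y numeric vectors of equal length.
#' @param n_bins number of bins, \code{2 <= n_bins <= length(x)/2}.
#' @return data.frame with \code{x_mean}, \code{y_mean}, \code{y_se},
#'   \code{n} per bin.
#' @export
bin_equal_count <- function(x, y, n_bins = 8) {
  stopifnot(length(x) == length(y))
  if (n_bins < 2 || n_bins > length(x) / 2)
    stop("n_bins must lie in [2, n/2]")
  if (length(unique(x)) == 1) {
    warning("degenerate x: all values equal, returning a single bin")
    return(data.frame(x_mean = x[1], y_mean = mean(y),
                      y_se = stats::sd(y) / sqrt(length(y)), n = length(y)))
  }
  ## stable rank order breaks ties deterministically at bin edges
  r <- rank(x, ties.method = "first")
  g <- ceiling(r / (length(x) / n_bins))
  g <- pmin(g, n_bins)
  agg <- function(v, f) as.numeric(tapply(v, g, f))
  data.frame(x_mean = agg(x, mean), y_mean = agg(y, mean),
             y_se = agg(y, function(v) stats::sd(v) / sqrt(length(v))),
             n = agg(x, length))
}

#' Split sample sizes into many/few reliability groups
#'
#' Labels each sample size by cumulative quantiles Q of the observed size
#' distribution. Scheme \code{"median"}: many > Q(0.5), few <= Q(0.5).
#' Scheme \code{"q60_40"}: many >= Q(0.6), few < Q(0.4), sizes in between
#' excluded.
#'
#' @param sizes integer vector of sample sizes.
#' @param scheme \code{"median"} or \code{"q60_40"}.
#' @return Character vector of labels \code{"many"}, \code{"few"},
#'   \code{"excluded"}.
#' @export
quantile_split <- function(sizes, scheme = c("median", "q60_40")) {
  if (length(sizes) == 0) stop("empty size vector")
  scheme <- match.arg(scheme)
  if (scheme == "median") {
    qs <- stats::quantile(sizes, 0.5, names = FALSE)
    ifelse(sizes > qs, "many", "few")
  } else {
    q60 <- stats::quantile(sizes, 0.6, names = FALSE)
    q40 <- stats::quantile(sizes, 0.4, names = FALSE)
    ifelse(sizes >= q60, "many", ifelse(sizes < q40, "few", "excluded"))
  }
}

## slope of aligned report on aligned standardized proportion by OLS,
## used for the conditional (many/few) contrasts
aligned_slope <- function(q_al, y_al) {
  unname(stats::coef(stats::lm(y_al ~ I(2 * (q_al - 0.5))))[2])
}

#' Pattern suite for the blocked task
#'
#' Computes the six qualitative signatures of hierarchical probabilistic
#' inference on a blocked response dataset (simulated or empirical), each as
#' a binned curve plus a scalar contrast with a predicted sign:
#' \describe{
#'   \item{tendency_effect}{confidence is higher in blue-tendency blocks at
#'     matched sample proportion (partial coefficient of b; predicted > 0).}
#'   \item{belief_effect}{aligned confidence increases with the
#'     ideal-observer aligned belief about the tendency from previous trials
#'     (slope; predicted > 0).}
#'   \item{current_size_effect}{the aligned confidence curve over the
#'     aligned sample proportion is steeper for large current samples
#'     (slope difference many - few; predicted > 0).}
#'   \item{previous_size_effect}{the modulation by the previous trial's
#'     aligned proportion is steeper when that sample was large (slope
#'     difference; predicted > 0).}
#'   \item{weight_equality}{regression weights of previous trials at
#'     position 5 are equal (maximum relative deviation from their mean;
#'     predicted small).}
#'   \item{position_trend}{aligned confidence increases with within-block
#'     position (slope; predicted > 0).}
#' }
#'
#' @param trials blocked trial table with \code{block_id}, \code{t},
#'   \code{N_B}, \code{N_R}, \code{N}, \code{q}, \code{b}, \code{y}. An
#'   \code{M1} column (belief from previous trials) is computed with the
#'   matched ideal observer if absent.
#' @param nu1,nu2 tendency shapes for the ideal-observer belief.
#' @param n_bins bins for the summary curves.
#' @return A list of class \code{"pattern_suite"} with one entry per
#'   pattern (each holding \code{contrast} and supporting detail) and a
#'   \code{contrasts} named vector.
#' @export
pattern_suite <- function(trials, nu1 = 14, nu2 = 9, n_bins = 8) {
  needed <- c("block_id", "t", "q", "b", "y", "N")
  if (!all(needed %in% names(trials)))
    stop("trials must carry columns ", paste(needed, collapse = ", "))
  if (!"M1" %in% names(trials))
    trials <- exp2_observer_batch(trials, nu1, nu2)
  y_al <- align_to_block(trials$y, trials$b)
  q_al <- align_to_block(trials$q, trials$b)
  M_al <- align_to_block(trials$M1, trials$b)

  ## 1. block-tendency effect at matched sample proportion
  fit_b <- stats::lm(y ~ I(2 * (q - 0.5)) + b, data = trials)
  tendency <- list(contrast = unname(stats::coef(fit_b)["b"]),
                   curve_blue = bin_equal_count(trials$q[trials$b == 1],
                                                trials$y[trials$b == 1], n_bins),
                   curve_red = bin_equal_count(trials$q[trials$b == 0],
                                               trials$y[trials$b == 0], n_bins))

  ## 2. aligned confidence vs optimally inferred aligned belief
  belief <- list(contrast = aligned_slope(M_al, y_al),
                 curve = bin_equal_count(M_al, y_al, n_bins))

  ## 3. current sample size conditional slopes
  grp <- quantile_split(trials$N, "median")
  s_many <- aligned_slope(q_al[grp == "many"], y_al[grp == "many"])
  s_few <- aligned_slope(q_al[grp == "few"], y_al[grp == "few"])
  current_size <- list(contrast = s_many - s_few,
                       slope_many = s_many, slope_few = s_few)

  ## 4. previous sample size conditional slopes (trials 2..5 on trial t-1)
  ord <- order(trials$block_id, trials$t)
  tr <- trials[ord, ]
  cur_rows <- which(tr$t >= 2)
  prev_rows <- cur_rows - 1
  ok <- tr$block_id[cur_rows] == tr$block_id[prev_rows]
  cur_rows <- cur_rows[ok]; prev_rows <- prev_rows[ok]
  qp_al <- align_to_block(tr$q[prev_rows], tr$b[prev_rows])
  yc_al <- align_to_block(tr$y[cur_rows], tr$b[cur_rows])
  pgrp <- quantile_split(tr$N[prev_rows], "median")
  p_many <- aligned_slope(qp_al[pgrp == "many"], yc_al[pgrp == "many"])
  p_few <- aligned_slope(qp_al[pgrp == "few"], yc_al[pgrp == "few"])
  previous_size <- list(contrast = p_many - p_few,
                        slope_many = p_many, slope_few = p_few)

  ## 5. equality of previous-trial regression weights at position 5
  w5 <- previous_trial_weights(trials, T = 5)
  wm <- mean(w5$weights)
  weight_eq <- list(contrast = max(abs(w5$weights - wm)) / abs(wm),
                    weights = w5$weights)

  ## 6. aligned confidence over within-block position
  pos_means <- tapply(y_al, trials$t, mean)
  position <- list(contrast = unname(stats::coef(stats::lm(y_al ~ trials$t))[2]),
                   means = pos_means)

  out <- list(tendency_effect = tendency, belief_effect = belief,
              current_size_effect = current_size,
              previous_size_effect = previous_size,
              weight_equality = weight_eq, position_trend = position)
  out$contrasts <- c(tendency_effect = tendency$contrast,
                     belief_effect = belief$contrast,
                     current_size_effect = current_size$contrast,
                     previous_size_effect = previous_size$contrast,
                     weight_equality = weight_eq$contrast,
                     position_trend = position$contrast)
  structure(out, class = "pattern_suite")
}

#' @export
print.pattern_suite <- function(x, ...) {
  cat("Hierarchical-inference pattern suite\n")
  print(round(x$contrasts, 4))
  cat("(signs predicted positive except weight_equality, predicted small)\n")
  invisible(x)
}
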