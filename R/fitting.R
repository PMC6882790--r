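#' Optimizer budget for model fitting
#'
#' Controls the seeded population (differential-evolution) stage and the
#' local refinement of every training run. Defaults favor robustness;
#' reduce \code{maxiter}/\code{pop} for quick exploratory fits.
#'
#' @param pop population size of the global stage (default 5 per parameter,
#'   at least 20).
#' @param maxiter generations of the global stage.
#' @param refine logical; run bounded L-BFGS-B refinement from the global
#'   optimum.
#' @return A list of class \code{"fit_control"}.
#' @export
fit_control <- function(pop = NULL, maxiter = 60, refine = TRUE) {
  structure(list(pop = pop, maxiter = maxiter, refine = refine),
            class = "fit_control")
}

#' Block-level cross-validation folds
#'
#' Partitions blocks (never single trials) into k near-equal folds at
#' random. Splitting at the block level keeps all trials sharing a hidden
#' context in the same fold.
#'
#' @param block_ids vector of block identifiers (one per block, unique).
#' @param k number of folds, \code{2 <= k <= length(block_ids)}.
#' @param seed integer seed.
#' @return Integer vector of fold labels in \code{1..k}, named by block id.
#' @export
cross_validate_folds <- function(block_ids, k = 10, seed = 1) {
  block_ids <- unique(block_ids)
  n <- length(block_ids)
  if (k < 2 || k > n) stop("k must lie in [2, number of blocks]")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  names(fold) <- block_ids
  fold
}

## ----- internal: per-model objective builders -------------------------------

## layout of the free-parameter vector for each model family
model_par_info <- function(model, experiment) {
  if (experiment == "exp1") {
    ## sigmoidal mapping on the internal estimate + noise SD
    list(names = c("w0", "w1", "w2", "theta"),
         lower = c(-50, -50, -50, 0.01), upper = c(50, 50, 50, 1))
  } else if (model == "mismatched") {
    ## sigmoid weights, noise SD, subjective tendency parameterized by its
    ## blue-context expectation e = nu1p/(nu1p + nu2p) >= 0.5 (enforcing
    ## nu1p >= nu2p) and concentration s = nu1p + nu2p
    list(names = c("w0", "w1", "w2", "theta", "expectation", "concentration"),
         lower = c(-50, -50, -50, 0.01, 0.5, 2),
         upper = c(50, 50, 50, 1, 0.95, 120))
  } else if (model == "difference") {
    list(names = c(paste0("w", 1:9), "theta", "omega"),
         lower = c(rep(-50, 9), 0.01, 0), upper = c(rep(50, 9), 1, 5))
  } else {
    list(names = c(paste0("w", 1:9), "theta"),
         lower = c(rep(-50, 9), 0.01), upper = c(rep(50, 9), 1))
  }
}

## Least-squares initializer for logistic-link mappings: regress the logit
## of the (clamped) responses on the design, and read the noise SD off the
## response-scale residuals. Lands local refinement in the right basin.
logit_ols_start <- function(X, y) {
  z <- stats::qlogis(pmin(pmax(y, 0.01), 0.99))
  w <- tryCatch(qr.solve(X, z), error = function(e) rep(0, ncol(X)))
  if (any(!is.finite(w))) w <- rep(0, ncol(X))
  th <- stats::sd(y - stats::plogis(drop(X %*% w)))
  c(w, min(max(th, 0.011), 0.99))
}

## Precompute whatever the likelihood needs once per dataset. Returns a
## closure factory: make(train_rows) -> list(nll(par), predict(par, rows)).
model_objective <- function(trials, model, experiment,
                            epsilon = default_epsilon(),
                            nu1 = 14, nu2 = 9, prior_a = 4, prior_b = 4) {
  y <- trials$y
  if (experiment == "exp1") {
    x <- switch(model,
      ideal = 2 * (exp1_confidence(trials$N_B, trials$N_R, prior_a,
                                   prior_b)$confidence_blue - 0.5),
      ratio = 2 * ratio_estimate(trials$N_B, trials$N_R) - 1,
      difference = difference_estimate_exp1(trials$N_B, trials$N_R),
      stop("unknown flat-condition model: ", model))
    make <- function(rows) {
      predict_rows <- function(par, r)
        sigmoid_map_raw(x[r], par[1:3])
      list(
        nll = function(par)
          -response_loglik(y[rows], predict_rows(par, rows), par[4], epsilon),
        test_ll = function(par, r)
          response_loglik(y[r], predict_rows(par, r), par[4], epsilon),
        starts = list(logit_ols_start(cbind(1, x[rows], x[rows]^3), y[rows])))
    }
    return(make)
  }
  if (model == "mismatched") {
    make <- function(rows) {
      predict_rows <- function(par, r) {
        nu1p <- par[5] * par[6]; nu2p <- (1 - par[5]) * par[6]
        conf <- exp2_observer_batch(trials, nu1p, nu2p)$confidence
        sigmoid_map_raw(2 * (conf[r] - 0.5), par[1:3])
      }
      list(
        nll = function(par)
          -response_loglik(y[rows], predict_rows(par, rows), par[4], epsilon),
        test_ll = function(par, r)
          response_loglik(y[r], predict_rows(par, r), par[4], epsilon))
    }
    return(make)
  }
  ## blocked condition, flexible mapping on (q, N, M)
  q <- trials$q; N <- trials$N
  if (model == "ideal") {
    M_fixed <- exp2_observer_batch(trials, nu1, nu2)$M1
  } else if (model %in% c("averaging", "tally")) {
    M_fixed <- heuristic_context_batch(trials, model)$M1
  } else if (model == "difference") {
    ## mean previous count difference per trial, recomputed under each omega
    d <- trials$N_B - trials$N_R
    n_prev <- stats::ave(rep(1, nrow(trials)), trials$block_id,
                         FUN = function(v) seq_along(v) - 1)
    cum_d <- stats::ave(d, trials$block_id,
                        FUN = function(v) c(0, cumsum(v)[-length(v)]))
    mean_prev_d <- ifelse(n_prev == 0, 0, cum_d / pmax(n_prev, 1))
    first <- n_prev == 0
  } else stop("unknown blocked-condition model: ", model)
  make <- function(rows) {
    if (model == "difference") {
      M1 <- ifelse(first, 0.5, stats::plogis(mean_prev_d))
      sc1 <- flexible_term_scales(q[rows], N[rows], M1[rows])
      X1 <- sweep(flexible_terms(q[rows], N[rows], M1[rows]), 2, sc1, "/")
      list(
        nll = function(par) {
          M <- ifelse(first, 0.5, stats::plogis(par[11] * mean_prev_d))
          sc <- flexible_term_scales(q[rows], N[rows], M[rows])
          yh <- flexible_map(q[rows], N[rows], M[rows], par[1:9], sc)
          -response_loglik(y[rows], yh, par[10], epsilon)
        },
        test_ll = function(par, r) {
          M <- ifelse(first, 0.5, stats::plogis(par[11] * mean_prev_d))
          sc <- flexible_term_scales(q[rows], N[rows], M[rows])
          yh <- flexible_map(q[r], N[r], M[r], par[1:9], sc)
          response_loglik(y[r], yh, par[10], epsilon)
        },
        starts = list(c(logit_ols_start(X1, y[rows]), 1)))
    } else {
      sc <- flexible_term_scales(q[rows], N[rows], M_fixed[rows])
      Xall <- sweep(flexible_terms(q, N, M_fixed), 2, sc, "/")
      list(
        nll = function(par)
          -response_loglik(y[rows],
                           stats::plogis(drop(Xall[rows, ] %*% par[1:9])),
                           par[10], epsilon),
        test_ll = function(par, r)
          response_loglik(y[r],
                          stats::plogis(drop(Xall[r, ] %*% par[1:9])),
                          par[10], epsilon),
        scales = sc,
        starts = list(logit_ols_start(Xall[rows, , drop = FALSE], y[rows])))
    }
  }
  make
}

## The mismatched-tendency likelihood has a curved ridge: expectation e and
## concentration s trade off at roughly constant separability of the two
## context components, delta(e, s) = (2e - 1) / sqrt(e (1 - e) / (s + 1)).
## A single local run can stall on the far end of that ridge, so refine from
## several starts that traverse it at the separability implied by the global
## optimum, keeping the best.
refine_along_tendency_ridge <- function(nll, opt, info) {
  e0 <- opt$par[5]; s0 <- opt$par[6]
  delta0 <- (2 * e0 - 1) / sqrt(e0 * (1 - e0) / (s0 + 1))
  best <- opt
  for (e in c(0.55, 0.6, 0.65, 0.7, 0.8, 0.9)) {
    s <- delta0^2 * e * (1 - e) / (2 * e - 1)^2 - 1
    s <- min(max(s, info$lower[6]), info$upper[6])
    start <- opt$par
    start[5] <- e; start[6] <- s
    loc <- tryCatch(
      stats::optim(start, nll, method = "L-BFGS-B", lower = info$lower,
                   upper = info$upper,
                   control = list(maxit = 500, factr = 1e7)),
      error = function(err) NULL)
    if (!is.null(loc) && is.finite(loc$value) && loc$value < best$value)
      best <- list(par = loc$par, value = loc$value,
                   converged = loc$convergence == 0)
  }
  best
}

#' Fit an observer + response-mapping model by maximum likelihood
#'
#' Maximizes the truncated-Gaussian-plus-lapse response likelihood over the
#' mapping weights, the noise SD theta (bounded below at 0.01) and any
#' model-specific parameters, using a seeded differential-evolution global
#' stage followed by bounded gradient refinement. With a fold assignment the
#' model is refit on each training set and evaluated on the held-out blocks;
#' the cross-validation log-likelihood (CVLL) is the median held-out
#' log-likelihood across folds.
#'
#' Flat-condition models (\code{experiment = "exp1"}): \code{"ideal"},
#' \code{"ratio"}, \code{"difference"}, each composed with the sigmoidal
#' mapping. Blocked-condition models: \code{"ideal"}, \code{"averaging"},
#' \code{"tally"}, \code{"difference"} feed their context estimate into the
#' flexible mapping; \code{"mismatched"} refits the hierarchical observer at
#' free subjective tendency shapes (nu1' >= nu2') with the sigmoidal
#' mapping.
#'
#' @param trials trial table with a \code{y} response column.
#' @param model model name, see Details.
#' @param experiment \code{"exp1"} or \code{"exp2"}.
#' @param folds optional fold assignment from [cross_validate_folds()]
#'   (names = block ids). \code{NULL} fits once on all data.
#' @param seed integer seed for the optimizer.
#' @param control a [fit_control()].
#' @param epsilon lapse floor (fixed, not fitted).
#' @param nu1,nu2,prior_a,prior_b generative shapes assumed by the matched
#'   ideal observer.
#' @param global_fit logical; also fit once on all data to report
#'   parameters. Set \code{FALSE} to save time when only the CVLL is needed
#'   (parameters are then taken from the first training fold).
#' @return A list of class \code{"hierconf_fit"}: \code{par} (named
#'   parameters from the all-data fit), \code{train_loglik},
#'   \code{fold_test_logliks}, \code{cvll} (median; \code{NA} without
#'   folds), \code{converged}, \code{model}, \code{experiment}.
#' @export
fit_model <- function(trials, model, experiment = c("exp2", "exp1"),
                      folds = NULL, seed = 1, control = fit_control(),
                      epsilon = default_epsilon(),
                      nu1 = 14, nu2 = 9, prior_a = 4, prior_b = 4,
                      global_fit = TRUE) {
  experiment <- match.arg(experiment)
  if (nrow(trials) == 0) stop("empty dataset")
  info <- model_par_info(model, experiment)
  make <- model_objective(trials, model, experiment, epsilon,
                          nu1, nu2, prior_a, prior_b)
  run <- function(rows, sd) {
    obj <- make(rows)
    opt <- global_then_local(obj$nll, info$lower, info$upper, seed = sd,
                             pop = control$pop, maxiter = control$maxiter,
                             refine = control$refine,
                             starts = if (is.null(obj$starts)) list()
                                      else obj$starts)
    if (model == "mismatched" && control$refine)
      opt <- refine_along_tendency_ridge(obj$nll, opt, info)
    list(obj = obj, opt = opt)
  }
  all_rows <- seq_len(nrow(trials))
  if (is.null(folds)) global_fit <- TRUE
  par <- NULL
  train_ll <- NA_real_
  converged <- TRUE
  if (global_fit) {
    fit_all <- run(all_rows, seed)
    par <- stats::setNames(fit_all$opt$par, info$names)
    train_ll <- -fit_all$opt$value
    converged <- fit_all$opt$converged
  }
  fold_ll <- numeric(0)
  if (!is.null(folds)) {
    ks <- sort(unique(folds))
    fold_of_trial <- folds[as.character(trials$block_id)]
    for (kk in ks) {
      test_rows <- which(fold_of_trial == kk)
      train_rows <- setdiff(all_rows, test_rows)
      f <- run(train_rows, seed + kk)
      converged <- converged && f$opt$converged
      fold_ll <- c(fold_ll, f$obj$test_ll(f$opt$par, test_rows))
      if (is.null(par)) par <- stats::setNames(f$opt$par, info$names)
    }
  }
  if (!converged)
    warning("optimizer did not report convergence for model ", model)
  structure(list(model = model, experiment = experiment, par = par,
                 train_loglik = train_ll,
                 fold_test_logliks = fold_ll,
                 cvll = if (length(fold_ll)) stats::median(fold_ll) else NA_real_,
                 converged = converged),
            class = "hierconf_fit")
}

#' @export
print.hierconf_fit <- function(x, ...) {
  cat("Model fit:", x$model, "(", x$experiment, ")\n")
  cat("  parameters:\n")
  print(round(x$par, 4))
  cat("  train log-likelihood:", format(x$train_loglik, digits = 6), "\n")
  if (length(x$fold_test_logliks))
    cat("  CVLL (median of", length(x$fold_test_logliks), "folds):",
        format(x$cvll, digits = 6), "\n")
  invisible(x)
}

#' Fit the mismatched-tendency observer
#'
#' Convenience wrapper around [fit_model()] for the hierarchical observer
#' with free subjective tendency shapes (nu1' >= nu2') and sigmoidal
#' response mapping. The subjective expectation of the blue-context
#' proportion, nu1'/(nu1' + nu2'), is the quantity of interest: values below
#' the generative 14/23 indicate that the fitted agent assumes a weaker
#' block tendency than the true one.
#'
#' @inheritParams fit_model
#' @return A \code{"hierconf_fit"} with additional entries \code{nu1p},
#'   \code{nu2p} and \code{tendency_expectation}.
#' @export
fit_mismatched_tendency <- function(trials, folds = NULL, seed = 1,
                                    control = fit_control(),
                                    epsilon = default_epsilon()) {
  fit <- fit_model(trials, "mismatched", "exp2", folds = folds, seed = seed,
                   control = control, epsilon = epsilon)
  fit$tendency_expectation <- unname(fit$par["expectation"])
  fit$nu1p <- unname(fit$par["expectation"] * fit$par["concentration"])
  fit$nu2p <- unname((1 - fit$par["expectation"]) * fit$par["concentration"])
  fit
}
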