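## Bounded, seeded differential evolution (rand/1/bin) for the global stage
## of model fitting. Minimizes fn over a box; deliberately small and
## dependency-free. Population initialized uniformly in the box; standard
## mutation factor and crossover rate.
de_optim <- function(fn, lower, upper, seed = 1, pop = NULL, maxiter = 60,
                     F = 0.8, CR = 0.9) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  if (is.null(pop)) pop <- max(20, 5 * d)
  set.seed(seed)
  X <- matrix(stats::runif(pop * d, rep(lower, each = pop),
                           rep(upper, each = pop)), nrow = pop)
  f <- apply(X, 1, fn)
  for (it in seq_len(maxiter)) {
    for (i in seq_len(pop)) {
      idx <- sample(setdiff(seq_len(pop), i), 3)
      v <- X[idx[1], ] + F * (X[idx[2], ] - X[idx[3], ])
      v <- pmin(pmax(v, lower), upper)
      cr <- stats::runif(d) < CR
      cr[sample.int(d, 1)] <- TRUE
      u <- ifelse(cr, v, X[i, ])
      fu <- fn(u)
      if (is.finite(fu) && fu <= f[i]) {
        X[i, ] <- u
        f[i] <- fu
      }
    }
  }
  best <- which.min(f)
  list(par = X[best, ], value = f[best])
}

## global DE stage followed by bounded local refinement from the DE optimum
## and any extra starting points (e.g. a least-squares initializer); the
## best refined solution wins
global_then_local <- function(fn, lower, upper, seed = 1, pop = NULL,
                              maxiter = 60, refine = TRUE, starts = list()) {
  g <- de_optim(fn, lower, upper, seed = seed, pop = pop, maxiter = maxiter)
  converged <- TRUE
  if (refine) {
    for (s0 in c(list(g$par), starts)) {
      s0 <- pmin(pmax(s0, lower), upper)
      loc <- tryCatch(
        stats::optim(s0, fn, method = "L-BFGS-B", lower = lower,
                     upper = upper,
                     control = list(maxit = 500, factr = 1e7)),
        error = function(e) NULL)
      if (!is.null(loc) && is.finite(loc$value) && loc$value <= g$value) {
        converged <- loc$convergence == 0
        g <- list(par = loc$par, value = loc$value)
      }
    }
  }
  c(g, list(converged = converged))
}
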