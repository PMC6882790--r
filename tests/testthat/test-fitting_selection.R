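test_that("block-level folds partition the blocks", {
  f <- cross_validate_folds(1:20, k = 10, seed = 1)
  expect_true(all(table(f) == 2))
  expect_identical(f, cross_validate_folds(1:20, k = 10, seed = 1))
  expect_setequal(names(f), as.character(1:20))
  expect_error(cross_validate_folds(1:5, k = 6), "k must lie")
  expect_error(cross_validate_folds(1:5, k = 1), "k must lie")
})

test_that("the training objective is a sum over trials", {
  tr <- sample_exp1_session(exp1_cfg, n_trials = 40, seed = 21)
  rr <- simulate_agent_responses(tr, agent_spec("ideal", "sigmoid",
                                                weights = c(0, 3, 0),
                                                theta = 0.08),
                                 seed = 22, config = exp1_cfg)
  make <- hierconf:::model_objective(rr, "ideal", "exp1")
  doubled <- rbind(rr, rr)
  doubled$block_id <- seq_len(nrow(doubled))
  make2 <- hierconf:::model_objective(doubled, "ideal", "exp1")
  par <- c(0.1, 2.5, -0.2, 0.1)
  nll1 <- make(seq_len(nrow(rr)))$nll(par)
  nll2 <- make2(seq_len(nrow(doubled)))$nll(par)
  expect_equal(nll2, 2 * nll1, tolerance = 1e-12)
})

test_that("folds of identically generated data give matching test log-likelihoods", {
  # two copies of the same session in different blocks: held-out fits agree
  tr <- sample_exp1_session(exp1_cfg, n_trials = 60, seed = 23)
  rr <- simulate_agent_responses(tr, agent_spec("ideal", "sigmoid",
                                                weights = c(0, 3, 0),
                                                theta = 0.1),
                                 seed = 24, config = exp1_cfg)
  dup <- rbind(rr, rr)
  dup$block_id <- c(rr$block_id, rr$block_id + 1000)
  folds <- c(rep(1L, 60), rep(2L, 60))
  names(folds) <- dup$block_id
  fit <- suppressWarnings(
    fit_model(dup, "ideal", "exp1", folds = folds, seed = 3,
              control = fit_control(maxiter = 30)))
  expect_length(fit$fold_test_logliks, 2)
  expect_equal(fit$fold_test_logliks[1], fit$fold_test_logliks[2],
               tolerance = 1e-3)
  expect_equal(fit$cvll, stats::median(fit$fold_test_logliks))
})

test_that("sigmoid-agent parameters are recovered from one session", {
  tr <- sample_exp1_session(exp1_cfg, n_trials = 280, seed = 31)
  rr <- simulate_agent_responses(tr, agent_spec("ideal", "sigmoid",
                                                weights = c(0, 3, 0),
                                                theta = 0.05),
                                 seed = 32, config = exp1_cfg)
  fit <- suppressWarnings(fit_model(rr, "ideal", "exp1", seed = 5))
  expect_lt(abs(fit$par["w1"] - 3) / 3, 0.2)
  expect_lt(abs(fit$par["theta"] - 0.05) / 0.05, 0.2)
})

test_that("the mismatched-tendency observer hits its constraint when the context is flat", {
  # no context signal: subjective shapes should collapse to near-equality
  cfg_flat <- generative_config("exp2", nu1 = 8, nu2 = 8)
  tr <- sample_exp2_session(cfg_flat, n_blocks = 80, seed = 41)
  rr <- simulate_agent_responses(tr, agent_spec("ideal", "identity",
                                                theta = 0.1),
                                 seed = 42, config = cfg_flat)
  fit <- suppressWarnings(
    fit_mismatched_tendency(rr, seed = 6,
                            control = fit_control(maxiter = 40)))
  expect_lt(abs(fit$tendency_expectation - 0.5), 0.05)
})

test_that("variational model selection behaves under symmetric and dominant evidence", {
  # identical evidence: uniform frequencies and exceedance
  L <- matrix(rep(c(-100, -100, -100), 6), nrow = 6, byrow = TRUE)
  res <- bms(L, seed = 2)
  expect_equal(unname(res$r), rep(1 / 3, 3), tolerance = 1e-8)
  expect_equal(res$p_exc, rep(1 / 3, 3), tolerance = 0.01)

  # one model dominant by 20+ log-units for every participant
  L2 <- cbind(rep(-80, 10), rep(-100, 10), rep(-105, 10))
  res2 <- bms(L2, seed = 2)
  expect_equal(unname(res2$u[, 1]), rep(1, 10), tolerance = 1e-6)
  expect_equal(unname(res2$alpha), c(11, 1, 1), tolerance = 1e-4)
  expect_gt(res2$p_exc[1], 0.99)

  # participant exchangeability
  res3 <- bms(L2[c(3, 1, 2, 4:10), ], seed = 2)
  expect_equal(res3$alpha, res2$alpha, tolerance = 1e-8)
  expect_error(bms(matrix(c(1, NA, 2, 3), 2)), "finite")
})

test_that("exceedance probabilities follow the Dirichlet tail", {
  expect_equal(exceedance_prob(c(1, 1)), c(0.5, 0.5))
  p <- exceedance_prob(c(5, 2))
  expect_gt(p[1], 0.5)
  expect_equal(p[1], stats::pbeta(0.5, 5, 2, lower.tail = FALSE))
  expect_equal(sum(p), 1)
  # symmetric three-model case by Monte-Carlo
  p3 <- exceedance_prob(c(2, 2, 2), n_mc = 2e5, seed = 3)
  expect_equal(p3, rep(1 / 3, 3), tolerance = 0.01)
  expect_equal(sum(p3), 1, tolerance = 1e-12)
  expect_error(exceedance_prob(c(1, -1)), "positive")
})

test_that("fitting is reproducible and robust across optimizer seeds", {
  tr <- sample_exp1_session(exp1_cfg, n_trials = 120, seed = 61)
  rr <- simulate_agent_responses(tr, agent_spec("ideal", "sigmoid",
                                                weights = c(0, 2.5, 0),
                                                theta = 0.08),
                                 seed = 62, config = exp1_cfg)
  f1 <- suppressWarnings(fit_model(rr, "ideal", "exp1", seed = 9))
  f2 <- suppressWarnings(fit_model(rr, "ideal", "exp1", seed = 9))
  expect_identical(f1$par, f2$par)
  # restart robustness: different optimizer seeds land on the same optimum
  f3 <- suppressWarnings(fit_model(rr, "ideal", "exp1", seed = 10))
  expect_lt(abs(f1$train_loglik - f3$train_loglik), 0.1)
})

test_that("fit results serialize to text and back", {
  tr <- sample_exp1_session(exp1_cfg, n_trials = 60, seed = 51)
  rr <- simulate_agent_responses(tr, agent_spec("ideal", "sigmoid",
                                                weights = c(0, 2, 0),
                                                theta = 0.1),
                                 seed = 52, config = exp1_cfg)
  fit <- suppressWarnings(fit_model(rr, "ratio", "exp1", seed = 7,
                                    control = fit_control(maxiter = 20)))
  path <- tempfile(fileext = ".tsv")
  write_fit(fit, path)
  back <- read_fit(path)
  expect_equal(back$par, fit$par)
  expect_equal(back$train_loglik, fit$train_loglik)
  expect_equal(back$model, fit$model)
})
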