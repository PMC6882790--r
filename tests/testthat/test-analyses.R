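test_that("block alignment is the tendency involution", {
  expect_equal(align_to_block(0.3, 0), 0.7)
  expect_equal(align_to_block(0.3, 1), 0.3)
  set.seed(61)
  x <- runif(20); b <- rbinom(20, 1, 0.5)
  expect_equal(align_to_block(align_to_block(x, b), b), x)
  expect_error(align_to_block(1.2, 1), "\\[0, 1\\]")
  expect_error(align_to_block(0.5, 2), "binary")
})

test_that("equal-count binning fills bins evenly and tracks the data", {
  x <- seq(0.005, 0.995, length.out = 100)
  bins <- bin_equal_count(x, x, n_bins = 4)
  expect_equal(bins$n, rep(25, 4))
  expect_equal(bins$x_mean, bins$y_mean)
  expect_warning(b1 <- bin_equal_count(rep(1, 10), runif(10), 2),
                 "degenerate")
  expect_equal(nrow(b1), 1)
  expect_error(bin_equal_count(x, x, 1), "n_bins")
  # deterministic tie handling at bin edges
  xt <- rep(c(1, 2), each = 10)
  expect_identical(bin_equal_count(xt, seq_along(xt), 2),
                   bin_equal_count(xt, seq_along(xt), 2))
})

test_that("quantile splits label sample sizes by reliability", {
  sizes <- rep(3:11, times = 40)
  lab <- quantile_split(sizes, "median")
  expect_setequal(unique(sizes[lab == "few"]), 3:7)
  expect_setequal(unique(sizes[lab == "many"]), 8:11)
  lab2 <- quantile_split(sizes, "q60_40")
  expect_true(all(c("many", "few", "excluded") %in% lab2))
  expect_true(all(quantile_split(rep(5, 10), "median") == "few"))
  expect_error(quantile_split(integer(0)), "empty")
})

test_that("confidence-curve slopes rise with sample size for a posterior observer", {
  tr <- sample_exp1_session(exp1_cfg, n_trials = 6000, seed = 71)
  rr <- simulate_agent_responses(tr, agent_spec("ideal", "identity",
                                                theta = 0.1),
                                 seed = 72, config = exp1_cfg)
  slopes <- sapply(seq(3, 13, 2), function(N)
    slope_by_sample_size(rr, N)$weights["omega"])
  expect_true(all(diff(slopes) > 0))

  # flat responses give a near-zero slope
  flat <- rr; flat$y <- 0.5 + rnorm(nrow(flat), 0, 0.01)
  flat$y <- pmin(pmax(flat$y, 0), 1)
  expect_lt(abs(slope_by_sample_size(flat, 7)$weights["omega"]), 0.1)

  # recoloring the data leaves the symmetric parameterization unchanged
  rec <- rr; rec$q <- 1 - rr$q; rec$y <- 1 - rr$y
  expect_equal(slope_by_sample_size(rec, 9)$weights,
               slope_by_sample_size(rr, 9)$weights, tolerance = 1e-4)
  expect_error(slope_by_sample_size(rr[1:5, ], 3), "at least")
})

test_that("previous-trial weights are balanced for the hierarchical observer", {
  dat <- pooled_ideal_agents(n_agents = 8, n_blocks = 350, seed = 400)
  w <- previous_trial_weights(dat, T = 5)
  expect_length(w$weights, 4)
  rel_spread <- max(abs(w$weights - mean(w$weights))) / abs(mean(w$weights))
  expect_lt(rel_spread, 0.15)

  # a context-blind agent (reports from the current sample only) shows only
  # the small residual loading that the intercept-free parameterization
  # assigns to the aligned-mean offset, far below the hierarchical
  # observer's weights
  tr <- sample_exp2_session(exp2_cfg, n_blocks = 2000, seed = 81)
  blind <- simulate_agent_responses(tr, agent_spec("ratio", "sigmoid",
                                                   weights = c(0, 2, 0),
                                                   theta = 0.1),
                                    seed = 82, config = exp2_cfg)
  w0 <- previous_trial_weights(blind, T = 5)
  expect_true(all(abs(w0$weights) < 0.35))
  expect_gt(min(w$weights), 2 * max(abs(w0$weights)))
  expect_error(previous_trial_weights(dat, T = 2), "T must be")
})

test_that("previous-trial influence accumulates only for the hierarchical observer", {
  # running-average heuristics keep the total influence of previous trials
  # roughly constant across block positions; probabilistic belief updating
  # makes it grow as evidence accumulates
  tr <- sample_exp2_session(exp2_cfg, n_blocks = 2000, seed = 95)
  avg <- simulate_agent_responses(
    tr, agent_spec("averaging", "flexible",
                   weights = c(0, 2, 0, 2, 0, 0, 0, 0, 0), theta = 0.1),
    seed = 97, config = exp2_cfg)
  idl <- simulate_agent_responses(tr, agent_spec("ideal", "identity",
                                                 theta = 0.1),
                                  seed = 98, config = exp2_cfg)
  growth <- function(d) {
    tot <- sapply(c(3, 5), function(T) sum(previous_trial_weights(d, T)$weights))
    tot[2] / tot[1] - 1
  }
  g_idl <- growth(idl)
  g_avg <- growth(avg)
  expect_gt(g_idl, 0.3)
  expect_lt(g_avg, 0.5 * g_idl)
})

test_that("evidence-opposing choices separate hierarchical from context-blind agents", {
  dat <- pooled_ideal_agents(n_agents = 8, n_blocks = 90, seed = 400)
  eo <- evidence_opposing_rate(dat, seed = 5)
  # the context-tracking observer opposes current evidence far more often
  # than response noise alone can explain
  expect_gt(eo$rate, eo$reference_rate)
  expect_lt(eo$reference_rate, 0.15)

  # a noiseless ratio agent never opposes the sample majority
  tr <- sample_exp2_session(exp2_cfg, n_blocks = 50, seed = 91)
  tr$y <- tr$q
  eo0 <- evidence_opposing_rate(tr, seed = 6)
  expect_equal(eo0$rate, 0)
  none <- tr[align_to_block(tr$q, tr$b) >= 0.5, ]
  expect_error(evidence_opposing_rate(none), "no trials")
})

test_that("the pattern suite separates hierarchical, heuristic and blind agents", {
  dat <- pooled_ideal_agents(n_agents = 8, n_blocks = 350, seed = 400)
  ps <- pattern_suite(dat)
  expect_gt(ps$contrasts["tendency_effect"], 0)
  expect_gt(ps$contrasts["belief_effect"], 0)
  expect_gt(ps$contrasts["current_size_effect"], 0)
  expect_gt(ps$contrasts["previous_size_effect"], 0)
  expect_gt(ps$contrasts["position_trend"], 0)

  # context-blind agent: no tendency separation, no position trend
  tr <- sample_exp2_session(exp2_cfg, n_blocks = 2000, seed = 95)
  blind <- simulate_agent_responses(tr, agent_spec("ratio", "sigmoid",
                                                   weights = c(0, 2, 0),
                                                   theta = 0.1),
                                    seed = 96, config = exp2_cfg)
  psb <- pattern_suite(blind)
  expect_lt(abs(psb$contrasts["tendency_effect"]), 0.03)
  expect_lt(abs(psb$contrasts["position_trend"]), 0.01)

  # averaging agent: previous-trial sample size does not modulate the
  # context estimate, so the conditional slopes nearly coincide
  avg <- simulate_agent_responses(
    tr, agent_spec("averaging", "flexible",
                   weights = c(0, 2, 0, 2, 0, 0, 0, 0, 0), theta = 0.1),
    seed = 97, config = exp2_cfg)
  psa <- pattern_suite(avg)
  expect_lt(abs(psa$contrasts["previous_size_effect"]),
            0.5 * ps$contrasts["previous_size_effect"])
  expect_error(pattern_suite(tr[, c("block_id", "t")]), "columns")
})

test_that("aligned analyses are invariant to a global recoloring", {
  dat <- pooled_ideal_agents(n_agents = 4, n_blocks = 60, seed = 500)
  rec <- dat
  rec$b <- 1 - dat$b
  rec$q <- 1 - dat$q
  rec$N_B <- dat$N_R; rec$N_R <- dat$N_B
  rec$y <- 1 - dat$y
  rec$M1 <- NULL; rec$confidence <- NULL; rec$m1 <- NULL
  w1 <- previous_trial_weights(dat, T = 4)
  w2 <- previous_trial_weights(rec, T = 4)
  expect_equal(w1$weights, w2$weights, tolerance = 1e-4)
  e1 <- evidence_opposing_rate(dat, seed = 8)
  e2 <- evidence_opposing_rate(rec, seed = 8)
  expect_equal(e1$rate, e2$rate)
})
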