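# Shared fixtures, built in code at test time.

exp1_cfg <- generative_config("exp1")
exp2_cfg <- generative_config("exp2")

# a blocked-condition dataset with ideal-agent responses, cached per size
.fixture_env <- new.env(parent = emptyenv())

ideal_exp2_responses <- function(n_blocks = 60, seed = 101, theta = 0.1) {
  key <- paste("ideal", n_blocks, seed, theta, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    tr <- sample_exp2_session(exp2_cfg, n_blocks = n_blocks, seed = seed)
    .fixture_env[[key]] <- simulate_agent_responses(
      tr, agent_spec("ideal", "identity", theta = theta),
      seed = seed + 1, config = exp2_cfg)
  }
  .fixture_env[[key]]
}

# pooled multi-agent dataset for pattern analyses
pooled_ideal_agents <- function(n_agents = 6, n_blocks = 60, seed = 300,
                                theta = 0.1) {
  key <- paste("pool", n_agents, n_blocks, seed, theta, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- do.call(rbind, lapply(seq_len(n_agents),
      function(p) {
        tr <- sample_exp2_session(exp2_cfg, n_blocks = n_blocks,
                                  seed = seed + p)
        tr$block_id <- paste0(p, "_", tr$block_id)
        simulate_agent_responses(tr,
                                 agent_spec("ideal", "identity", theta = theta),
                                 seed = seed + 1000 + p, config = exp2_cfg)
      }))
  }
  .fixture_env[[key]]
}

# independent trapezoid quadrature used as an oracle in several tests
trapz_quad <- function(f, lower, upper, n = 1e5) {
  x <- seq(lower, upper, length.out = n)
  sum((f(x)[-1] + f(x)[-n]) / 2) * (x[2] - x[1])
}
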