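test_that("simulation is reproducible from its seed", {
  env <- fixture_env
  plan <- small_plan(seed = 2)
  a <- simulate_agent(env, agent_parameters(), plan, seed = 7)
  b <- simulate_agent(env, agent_parameters(), plan, seed = 7)
  expect_identical(a$trials, b$trials)
  expect_identical(a$trace, b$trace)
  c <- simulate_agent(env, agent_parameters(), plan, seed = 8)
  expect_false(identical(a$trials, c$trials))
})

test_that("the engine and the R step functions walk the same path", {
  env <- fixture_env
  plan <- small_plan(seed = 3)
  sim <- simulate_agent(env, agent_parameters(), plan, seed = 3)
  ref <- reference_replay(env, agent_parameters(), sim$trials)
  rep <- replay_agent(sim$trials, agent_parameters(), env, "arbitrating")

  for (col in c("p_mb", "chi_mf", "chi_mb", "omega", "ope1", "ope2",
                "spe1", "spe2", "prob_a0", "prob_a1")) {
    expect_equal(sim$trace[[col]], ref$trace[[col]], tolerance = 1e-10,
                 label = paste("simulated", col))
    expect_equal(rep$trace[[col]], ref$trace[[col]], tolerance = 1e-10,
                 label = paste("replayed", col))
  }
  expect_equal(sim$trace$qmf_s0_l, ref$trace$qmf_s0_l, tolerance = 1e-10)
  expect_equal(sim$trace$qmb_s0_l, ref$trace$qmb_s0_l, tolerance = 1e-10)
  expect_equal(rep$nll, ref$nll, tolerance = 1e-8)
})

test_that("a random agent's success rate matches the enumerated baseline", {
  env <- fixture_env
  p_succ <- attr(outcome_distribution(env, "flexible", "low"), "p_success")
  shocks <- unlist(lapply(1:5, function(s) {
    sim <- simulate_agent(env, agent_parameters(kind = "random"),
                          generate_session_plan(seed = s + 60), seed = s)
    tr <- sim$trials
    tr$shocks[tr$session != "training" & tr$condition == "flexible" &
                tr$uncertainty == "low"]
  }))
  se <- sqrt(p_succ * (1 - p_succ) / length(shocks))
  expect_lt(abs(mean(shocks == 0) - p_succ), 3 * se)
})

test_that("a model-based agent holding the true transition model is near-optimal", {
  env <- fixture_env
  t_true <- matrix(0.9, 5, 2) # low-uncertainty truth
  params <- agent_parameters(alpha = 0.01, beta = 20, kind = "mb_only",
                             t_init = t_true)
  cfg <- default_task_config()
  cfg$blocks_per_cell <- 8L
  plan <- generate_session_plan(cfg, seed = 12, include_training = FALSE)
  plan <- plan[plan$uncertainty == "low", ]
  sim <- simulate_agent(env, params, plan, seed = 12)
  perf <- performance_metrics(sim$trials, env)
  opt <- perf$mean[perf$metric == "optimal" & perf$uncertainty == "low"]
  expect_true(all(opt > 0.95))
})

test_that("the ideal policy reproduces the condition structure of the task", {
  env <- fixture_env
  # flexible: same first-stage optimum under both uncertainty levels,
  # different second-stage optimum at the likely intermediate state
  low <- ideal_agent_policy(env, "flexible", "low")
  high <- ideal_agent_policy(env, "flexible", "high")
  expect_identical(low[["S0"]], high[["S0"]])
  expect_identical(low[["S0"]], "R")
  expect_identical(low[["I3"]], "R")
  expect_identical(high[["I3"]], "L")

  # goal-chasing: the policy steers towards the goal coin when it can
  blue <- ideal_agent_policy(env, "specific", "low", "blue")
  expect_identical(blue[["I1"]], "R") # blue likely via I1-R
  expect_identical(blue[["I2"]], "L")
})

test_that("arbitrating agents weight the planner more under specific goals", {
  env <- fixture_env
  sep <- vapply(1:4, function(s) {
    sim <- simulate_agent(env, agent_parameters(),
                          generate_session_plan(seed = s + 70), seed = s)
    k <- sim$trials$session != "training"
    mean(sim$trace$p_mb[k & sim$trials$condition == "specific"]) -
      mean(sim$trace$p_mb[k & sim$trials$condition == "flexible"])
  }, 0)
  expect_gt(mean(sep), 0)
})

test_that("cohorts are reproducible and stash true parameters", {
  a <- simulate_cohort(3, default_param_sampler, small_config(), seed = 5)
  b <- simulate_cohort(3, default_param_sampler, small_config(), seed = 5)
  expect_identical(lapply(a, `[[`, "trials"), lapply(b, `[[`, "trials"))
  expect_length(unique(vapply(a, `[[`, 0, "seed")), 3)
  expect_s3_class(a[[1]]$params, "agent_parameters")
  expect_error(simulate_cohort(0), "n_subjects")
})

test_that("penalising trials carry computer choices and are flagged", {
  env <- fixture_env
  params <- agent_parameters(miss_prob = 0.2)
  sim <- simulate_agent(env, params, small_plan(seed = 4), seed = 4)
  expect_gt(sum(sim$trials$excluded), 0)
  expect_true(all(is.na(sim$trace$ll[sim$trials$excluded])))
  expect_true(all(!is.na(sim$trace$ll[!sim$trials$excluded])))
})
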