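test_that("ideal agents are scored as fully optimal; random agents at chance", {
  env <- fixture_env
  ideal <- lapply(1:2, function(s)
    simulate_agent(env, agent_parameters(kind = "ideal"),
                   generate_session_plan(seed = s + 20), seed = s)$trials)
  perf <- performance_metrics(ideal, env)
  expect_true(all(perf$mean[perf$metric == "optimal"] == 1))
  expect_true(all(perf$ideal[perf$metric == "optimal"] == 1))

  rnd <- lapply(1:3, function(s)
    simulate_agent(env, agent_parameters(kind = "random"),
                   generate_session_plan(seed = s + 30), seed = s)$trials)
  perf <- performance_metrics(rnd, env)
  opt <- perf[perf$metric %in% c("optimal_stage1", "optimal_stage2"), ]
  expect_true(all(abs(opt$mean - 0.5) < 0.1))
  # success rates sit on the enumerated random baseline
  succ <- perf[perf$metric == "success_rate", ]
  expect_true(all(abs(succ$mean - succ$random) < 0.1))
  # the flexible condition and low uncertainty are inherently easier
  base <- succ$random
  names(base) <- paste(succ$condition, succ$uncertainty)
  expect_gt(base[["flexible low"]], base[["specific low"]])
  expect_gt(base[["flexible low"]], base[["flexible high"]])
})

test_that("the alternative success definition counts any avoided maximum", {
  env <- fixture_env
  tr <- simulate_agent(env, agent_parameters(),
                       generate_session_plan(seed = 25), seed = 25)$trials
  zero <- performance_metrics(tr, env)
  lt4 <- performance_metrics(tr, env, success_rule = "lt4")
  z <- zero$mean[zero$metric == "success_rate"]
  l <- lt4$mean[lt4$metric == "success_rate"]
  expect_true(all(l >= z))
  # enumerated baselines follow the same rule
  d <- outcome_distribution(env, "flexible", "low", success_rule = "lt4")
  expect_equal(attr(d, "p_success"), 1 - d[["4"]])
  expect_true(all(lt4$random[lt4$metric == "success_rate"] >=
                    zero$random[zero$metric == "success_rate"]))
})

test_that("summaries are invariant to subject order", {
  env <- fixture_env
  tl <- lapply(1:3, function(s)
    simulate_agent(env, agent_parameters(),
                   generate_session_plan(seed = s + 40), seed = s)$trials)
  a <- performance_metrics(tl, env)
  b <- performance_metrics(rev(tl), env)
  expect_equal(a$mean, b$mean)
  expect_equal(a$sem, b$sem)
})

test_that("identical per-trial likelihoods give a zero regime statistic", {
  env <- fixture_env
  sim <- simulate_agent(env, agent_parameters(), small_plan(seed = 8),
                        seed = 8)
  u <- agent_parameters(beta = 0) # uniform under either pinned controller
  rlr <- likelihood_ratio_regimes(sim$trials, sim$trace, u, u, env)
  expect_equal(unname(rlr$statistic), c(0, 0))
  keep <- sim$trials$session != "training" & !sim$trials$excluded
  expect_equal(sum(rlr$n_trials), sum(keep))
})

test_that("excluded trials enter neither metrics nor regime statistics", {
  env <- fixture_env
  sim <- simulate_agent(env, agent_parameters(miss_prob = 0.15),
                        small_plan(seed = 9), seed = 9)
  u <- agent_parameters(beta = 0)
  rlr <- likelihood_ratio_regimes(sim$trials, sim$trace, u, u, env)
  keep <- sim$trials$session != "training" & !sim$trials$excluded
  expect_equal(nrow(rlr$per_trial), sum(keep))
  expect_false(any(sim$trials$trial[sim$trials$excluded] %in%
                     rlr$per_trial$trial))
  expect_error(likelihood_ratio_regimes(sim$trials, sim$trace[-1, ], u, u,
                                        env), "length")
})

test_that("regime statistics separate data generated by each controller", {
  env <- fixture_env
  stats <- t(vapply(1:4, function(s) {
    kind <- if (s %% 2 == 0) "mf_only" else "mb_only"
    gen <- agent_parameters(kind = kind, beta = 4)
    sim <- simulate_agent(env, gen, generate_session_plan(seed = s + 50),
                          seed = s)
    arbtrace <- replay_agent(sim$trials, agent_parameters(), env)$trace
    mf <- fit_parameters(sim$trials, env, "mf_only", n_restarts = 3, seed = s)
    mb <- fit_parameters(sim$trials, env, "mb_only", n_restarts = 3, seed = s)
    rlr <- likelihood_ratio_regimes(sim$trials, arbtrace, mf, mb, env)
    c(total = sum(rlr$statistic), mf_gen = kind == "mf_only")
  }, c(0, 0)))
  # MB-minus-MF log likelihood: negative for MF-generated data, positive
  # for MB-generated data
  expect_true(all(stats[stats[, "mf_gen"] == 1, "total"] < 0))
  expect_true(all(stats[stats[, "mf_gen"] == 0, "total"] > 0))
})

test_that("group comparisons behave on identical, distinct and bad input", {
  env <- fixture_env
  fake_fit <- function(par) {
    structure(list(variant = "mf_only", par = par, nll = 0), class = "avoid_fit")
  }
  a <- lapply(c(0.2, 0.3, 0.4), function(x)
    fake_fit(c(alpha = x, beta = 2 * x)))
  same <- compare_parameter_groups(a, a, paired = TRUE)
  expect_equal(same$p_value, c(1, 1))
  expect_equal(same$statistic, c(0, 0))

  b <- lapply(c(0.5, 0.7, 0.9), function(x)
    fake_fit(c(alpha = x, beta = 2 * x)))
  diff <- compare_parameter_groups(a, b)
  expect_true(all(diff$mean_b > diff$mean_a))
  expect_true(all(diff$p_value < 1))

  expect_error(compare_parameter_groups(a[1], b), "at least 2")
  bad <- lapply(c(0.2, 0.3), function(x) fake_fit(c(alpha = x)))
  expect_error(compare_parameter_groups(a, bad), "different parameter sets")
})

test_that("a large group difference in the reliability rate is detected", {
  env <- fixture_env
  fit_group <- function(beta, seed0) {
    lapply(1:4, function(s) {
      gen <- agent_parameters(kind = "mf_only", beta = beta)
      sim <- simulate_agent(env, gen,
                            generate_session_plan(seed = seed0 + s),
                            seed = seed0 + s)
      fit_parameters(sim$trials, env, "mf_only", n_restarts = 3,
                     seed = seed0 + s)
    })
  }
  low <- fit_group(beta = 2, seed0 = 100)
  high <- fit_group(beta = 8, seed0 = 200)
  tab <- compare_parameter_groups(low, high)
  beta_row <- tab[tab$parameter == "beta", ]
  expect_gt(beta_row$mean_b, beta_row$mean_a)
  expect_lt(beta_row$p_value, 0.05)
})
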