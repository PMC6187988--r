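test_that("single SARSA updates follow the prediction-error rule", {
  env <- fixture_env
  mf <- mf_init(env, alpha = 0.5)
  res <- mf_update(mf, "I3", "R", r = -4)
  expect_equal(res$ope, -4)
  expect_equal(res$mf$q["I3", "R"], -2)

  # a vanishing learning rate freezes the values but still reports the error
  mf <- mf_init(env, alpha = 1e-12)
  res <- mf_update(mf, "I3", "R", r = -4)
  expect_equal(res$ope, -4)
  expect_equal(res$mf$q["I3", "R"], 0, tolerance = 1e-10)

  expect_error(mf_init(env, alpha = 0), "alpha")
  expect_error(mf_init(env, alpha = 1.5), "alpha")
})

test_that("a three-trial SARSA sequence matches the arithmetic ledger", {
  # ledger (alpha = 0.2), computed by hand before implementation:
  # trial 1: Q(S0,L): ope 0;        Q(I1,L): ope -1   -> -0.2
  # trial 2: Q(S0,L): ope -0.2  -> -0.04
  #          Q(I1,L): ope -3.8  -> -0.96
  # trial 3: Q(S0,L): ope -0.92 -> -0.224
  #          Q(I1,L): ope 0.96  -> -0.768
  mf <- mf_init(fixture_env, alpha = 0.2)
  rs <- c(-1, -4, 0)
  for (r in rs) {
    mf <- mf_update(mf, "S0", "L", 0, "I1", "L")$mf
    mf <- mf_update(mf, "I1", "L", r)$mf
  }
  expect_equal(mf$q["S0", "L"], -0.224)
  expect_equal(mf$q["I1", "L"], -0.768)
})

test_that("transition updates move probability to the observed successor", {
  env <- fixture_env
  mb <- mb_init(env, alpha = 0.2)
  res <- mb_update_transition(mb, "S0", "L", "I1") # likely successor
  expect_equal(res$spe, 0.5)
  expect_equal(res$mb$p_likely["S0", "L"], 0.6)

  mb2 <- res$mb
  mb2$p_likely["S0", "L"] <- 1
  res2 <- mb_update_transition(mb2, "S0", "L", "I1")
  expect_equal(res2$spe, 0)
  expect_equal(res2$mb$p_likely["S0", "L"], 1)

  expect_error(mb_update_transition(mb, "S0", "L", "O1"), "not configured")
})

test_that("repeated observation of one successor converges T to its rate", {
  mb <- mb_init(fixture_env, alpha = 0.1)
  for (i in 1:200) mb <- mb_update_transition(mb, "I2", "R", "O1")$mb
  expect_lt(abs(mb$p_likely["I2", "R"] - 1), 0.02)
  # closed form of the recursion: 1 - (1 - alpha)^n * (1 - T0)
  expect_equal(mb$p_likely["I2", "R"], 1 - 0.9^200 * 0.5, tolerance = 1e-12)
})

test_that("T rows remain probabilities under arbitrary update sequences", {
  set.seed(21)
  mb <- mb_init(fixture_env, alpha = 0.7)
  tr <- fixture_env$transitions
  for (i in 1:500) {
    k <- sample(nrow(tr), 1)
    obs <- if (runif(1) < 0.5) tr$likely[k] else tr$unlikely[k]
    mb <- mb_update_transition(mb, tr$state[k], tr$action[k], obs)$mb
  }
  expect_true(all(mb$p_likely >= 0 & mb$p_likely <= 1))
  tab <- mb_transition_table(mb)
  sums <- tapply(tab$prob, paste(tab$state, tab$action), sum)
  expect_equal(as.numeric(sums), rep(1, 10), tolerance = 1e-10)
})

test_that("backward induction agrees with exhaustive expectimax", {
  env <- fixture_env
  # uniform transition model, face-value terminals: closed-form values
  mb <- mb_init(env)
  expect_equal(mb$q["S0", "L"], -2)
  expect_equal(mb$q["S0", "R"], -1.5)
  expect_equal(mb$q["I1", "L"], -2.5)

  # deterministic transition model: the better action is exact
  mb$p_likely[] <- 1
  mb <- mb_compute_values(mb)
  expect_equal(mb$q["I3", "R"], 0)  # leads to the red 0-shock coin surely

  set.seed(31)
  for (rep in 1:50) {
    plik <- matrix(runif(10), 5, 2,
                   dimnames = list(env$choice_states, env$actions))
    term <- setNames(-runif(4, 0, 4), env$outcome_states)
    mb$p_likely <- plik
    mb$term <- term
    mb <- mb_compute_values(mb)
    expect_equal(mb$q, oracle_expectimax(env, plik, term), tolerance = 1e-10)
  }
})

test_that("goal devaluation rewrites terminal values and replans", {
  env <- fixture_env
  mb <- mb_init(env)
  red <- devalue_outcomes(mb, "specific", "red")
  expect_equal(unname(red$term), c(0, -4, -4, -4))
  flex <- devalue_outcomes(mb, "flexible")
  expect_equal(unname(flex$term), c(0, -1, -2, -4))
  expect_error(devalue_outcomes(mb, "specific", "grey"), "goal colour")

  yellow <- devalue_outcomes(mb, "specific", "yellow")
  blue <- devalue_outcomes(mb, "specific", "blue")
  # consecutive goal changes replan toward different coins
  expect_false(identical(yellow$q, blue$q))
  expect_equal(yellow$q, oracle_expectimax(env, yellow$p_likely, yellow$term),
               tolerance = 1e-10)
})

test_that("model-free values ignore the goal sequence when experience is fixed", {
  env <- fixture_env
  set.seed(41)
  plan <- small_plan(seed = 6)
  sim <- simulate_agent(env, agent_parameters(), plan, seed = 6)
  tr <- sim$trials
  run_mf <- function(goals) {
    mf <- mf_init(env, alpha = 0.3)
    mb <- mb_init(env, alpha = 0.3)
    qmb_trace <- numeric(nrow(tr))
    for (i in seq_len(nrow(tr))) {
      mb <- devalue_outcomes(mb, tr$condition[i],
                             if (tr$condition[i] == "specific") goals[i]
                             else "white")
      qmb_trace[i] <- mb$q["S0", "L"]
      mf <- mf_update(mf, "S0", tr$a0[i], 0, tr$s1[i], tr$a1[i])$mf
      # experience held fixed: the delivered shocks come from the log
      mf <- mf_update(mf, tr$s1[i], tr$a1[i], -tr$shocks[i])$mf
    }
    list(q = mf$q, qmb = qmb_trace)
  }
  spec_idx <- which(tr$condition == "specific")
  goals_perm <- tr$goal
  set.seed(42)
  goals_perm[spec_idx] <- sample(goals_perm[spec_idx])
  a <- run_mf(tr$goal)
  b <- run_mf(goals_perm)
  expect_identical(a$q, b$q)          # MF cannot "see ahead" to the goal
  expect_false(identical(a$qmb, b$qmb)) # MB replans with the goal
})

test_that("model-free prediction errors shrink in a stationary environment", {
  env <- fixture_env
  cfg <- small_config()
  cfg$blocks_per_cell <- 2L
  cfg$training_trials <- 500L
  plan <- generate_session_plan(cfg, seed = 8)
  plan <- plan[plan$session == "training", ]
  sim <- simulate_agent(env, agent_parameters(kind = "mf_only", beta = 2),
                        plan, seed = 8)
  ab <- abs(sim$trace$ope2)
  expect_lt(mean(ab[451:500]), mean(ab[1:50]))
})
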