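# Shared fixtures and independent oracles, all built in code.

fixture_env <- build_environment()

# A short experiment: 2 blocks per cell over 2 sessions, 10 training trials.
small_config <- function() {
  cfg <- default_task_config()
  cfg$blocks_per_cell <- 2L
  cfg$training_trials <- 10L
  cfg
}

small_plan <- function(seed = 1) generate_session_plan(small_config(), seed = seed)

# Independent expectimax oracle: explicit enumeration over first actions,
# intermediate states, second actions and outcome states, written with
# scalar loops (no shared code with the package's backward induction).
oracle_expectimax <- function(env, p_likely_mat, term) {
  tr <- env$transitions
  succ_of <- function(s, a) {
    row <- tr[tr$state == s & tr$action == a, ]
    c(row$likely, row$unlikely)
  }
  p_of <- function(s, a) {
    p <- p_likely_mat[s, a]
    c(p, 1 - p)
  }
  q <- matrix(NA_real_, 5, 2, dimnames = list(env$choice_states, env$actions))
  for (s in env$choice_states[2:5]) {
    for (a in env$actions) {
      ss <- succ_of(s, a)
      pp <- p_of(s, a)
      total <- 0
      for (j in 1:2) total <- total + pp[j] * term[[ss[j]]]
      q[s, a] <- total
    }
  }
  for (a in env$actions) {
    ss <- succ_of("S0", a)
    pp <- p_of("S0", a)
    total <- 0
    for (j in 1:2) {
      best <- -Inf
      for (a1 in env$actions) if (q[ss[j], a1] > best) best <- q[ss[j], a1]
      total <- total + pp[j] * best
    }
    q["S0", a] <- total
  }
  q
}

# Brute-force rule table for outcome delivery, written as a plain if-chain.
oracle_delivery <- function(coin_colour, coin_value, condition, goal_colour) {
  if (condition == "flexible") return(coin_value)
  if (coin_colour == goal_colour) return(coin_value)
  4
}

# Reference replay built from the exported R step functions, mirroring the
# documented within-trial order of operations. Used to cross-check the
# compiled engine trace and likelihood.
reference_replay <- function(env, params, trials) {
  mf <- mf_init(env, params$alpha)
  mb <- mb_init(env, params$alpha)
  rel <- reliability_init(params$eta, params$omega, params$omega_max,
                          params$zspe0)
  arb <- arbitration_init(params$amp_mf_to_mb, params$amp_mb_to_mf,
                          params$B, params$bias_mf, params$p_mb0)
  map <- env$outcome_map
  n <- nrow(trials)
  out <- data.frame(p_mb = numeric(n), chi_mf = numeric(n),
                    chi_mb = numeric(n), omega = numeric(n),
                    ope1 = numeric(n), ope2 = numeric(n),
                    spe1 = numeric(n), spe2 = numeric(n),
                    prob_a0 = numeric(n), prob_a1 = numeric(n),
                    qmf_s0_l = numeric(n), qmb_s0_l = numeric(n))
  nll <- 0
  for (i in seq_len(n)) {
    cond <- trials$condition[i]
    goal <- trials$goal[i]
    mb <- devalue_outcomes(mb, cond, if (cond == "specific") goal else "white")
    p_eff <- arb$p_mb
    q0 <- integrate_values(mf$q["S0", ], mb$q["S0", ], p_eff)
    pr0 <- softmax_choice_prob(q0, params$beta)
    a0 <- trials$a0[i]
    out$qmf_s0_l[i] <- mf$q["S0", "L"]
    out$qmb_s0_l[i] <- mb$q["S0", "L"]

    s1 <- trials$s1[i]
    upd <- mb_update_transition(mb, "S0", a0, s1)
    mb <- upd$mb
    rel <- update_mb_reliability(rel, upd$spe)
    out$spe1[i] <- upd$spe

    q1 <- integrate_values(mf$q[s1, ], mb$q[s1, ], p_eff)
    pr1 <- softmax_choice_prob(q1, params$beta)
    a1 <- trials$a1[i]

    updmf <- mf_update(mf, "S0", a0, 0, s1, a1)
    mf <- updmf$mf
    rel <- update_mf_reliability(rel, updmf$ope)
    out$ope1[i] <- updmf$ope

    s2 <- trials$s2[i]
    upd <- mb_update_transition(mb, s1, a1, s2)
    mb <- upd$mb
    rel <- update_mb_reliability(rel, upd$spe)
    out$spe2[i] <- upd$spe

    idx <- match(s2, map$state)
    r <- -deliver_outcome(map$colour[idx], map$shocks[idx], cond,
                          if (cond == "specific") goal else "red")
    updmf <- mf_update(mf, s1, a1, r)
    mf <- updmf$mf
    rel <- update_mf_reliability(rel, updmf$ope)
    out$ope2[i] <- updmf$ope

    arb <- update_controller_weight(arb, rel$chi_mf, rel$chi_mb)
    out$p_mb[i] <- p_eff
    out$chi_mf[i] <- rel$chi_mf
    out$chi_mb[i] <- rel$chi_mb
    out$omega[i] <- rel$Omega
    out$prob_a0[i] <- pr0[[a0]]
    out$prob_a1[i] <- pr1[[a1]]
    if (trials$session[i] != "training" && !trials$excluded[i])
      nll <- nll - log(max(pr0[[a0]], 1e-12)) - log(max(pr1[[a1]], 1e-12))
  }
  list(trace = out, nll = nll)
}
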