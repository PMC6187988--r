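.trace_cols <- c("p_mb", "chi_mf", "chi_mb", "omega", "ope1", "ope2",
                 "spe1", "spe2", "prob_a0", "prob_a1", "ll",
                 "qmf_s0_l", "qmf_s0_r", "qmb_s0_l", "qmb_s0_r",
                 "qmf_s1_l", "qmf_s1_r", "qmb_s1_l", "qmb_s1_r")

#' Agent parameters for the dual-system model
#'
#' Bundles the six free parameters of the arbitration model -- the shared
#' learning rate `alpha`, the reliability learning rate `eta`, the zero-SPE
#' threshold `omega`, the two transition-rate amplitudes and the softmax
#' inverse temperature `beta` -- together with the fixed constants (logistic
#' steepness `B`, model-free bias multiplier, OPE normaliser `omega_max`,
#' starting weight and zero-SPE rate) and the agent kind.
#'
#' @param alpha Shared learning rate of both value systems, in (0, 1].
#' @param eta Learning rate of the reliability estimators, in (0, 1].
#' @param omega Zero-SPE threshold in (0, 1).
#' @param amp_mf_to_mb,amp_mb_to_mf Positive transition-rate amplitudes.
#' @param beta Softmax inverse temperature, >= 0.
#' @param kind Agent kind: `"arbitrating"` (dynamic weight), `"mf_only"`
#'   (weight pinned at 0), `"mb_only"` (pinned at 1), `"random"` (uniform
#'   choice, i.e. `beta = 0`) or `"ideal"` (expectimax on the true task).
#' @param B Fixed logistic steepness of the transition rates.
#' @param bias_mf Fixed multiplier (>= 1) on the MB-to-MF rate.
#' @param omega_max Normaliser of the model-free reliability.
#' @param p_mb0 Starting weight on the model-based controller.
#' @param zspe0 Starting zero-SPE rate.
#' @param miss_prob Per-trial probability of a penalising (missed) trial in
#'   simulation: both choices are made uniformly at random by the computer
#'   and the trial is flagged excluded.
#' @param t_init Optional 5 x 2 matrix of starting probabilities of the
#'   designated likely successor (default uniform 0.5); rows are the choice
#'   states, columns the actions. Setting the true probabilities yields an
#'   agent with a correct transition model from the outset.
#' @return A list of class `agent_parameters`.
#' @export
agent_parameters <- function(alpha = 0.5, eta = 0.5, omega = 0.45,
                             amp_mf_to_mb = 0.5, amp_mb_to_mf = 0.3,
                             beta = 3,
                             kind = c("arbitrating", "mf_only", "mb_only",
                                      "random", "ideal"),
                             B = 10, bias_mf = 1.5, omega_max = 4,
                             p_mb0 = 0.5, zspe0 = 0.5, miss_prob = 0,
                             t_init = NULL) {
  kind <- match.arg(kind)
  .check_alpha(alpha)
  if (eta <= 0 || eta > 1) stop("eta must lie in (0, 1]")
  if (omega <= 0 || omega >= 1) stop("omega must lie in (0, 1)")
  if (amp_mf_to_mb <= 0 || amp_mb_to_mf <= 0)
    stop("transition-rate amplitudes must be positive")
  if (beta < 0) stop("beta must be >= 0")
  if (miss_prob < 0 || miss_prob >= 1) stop("miss_prob must lie in [0, 1)")
  if (!is.null(t_init)) {
    t_init <- as.matrix(t_init)
    if (!all(dim(t_init) == c(5, 2)) || any(t_init < 0) || any(t_init > 1))
      stop("t_init must be a 5 x 2 matrix of probabilities")
  }
  structure(
    list(alpha = alpha, eta = eta, omega = omega,
         amp_mf_to_mb = amp_mf_to_mb, amp_mb_to_mf = amp_mb_to_mf,
         beta = beta, kind = kind, B = B, bias_mf = bias_mf,
         omega_max = omega_max, p_mb0 = p_mb0, zspe0 = zspe0,
         miss_prob = miss_prob, t_init = t_init),
    class = "agent_parameters"
  )
}

#' @export
print.agent_parameters <- function(x, ...) {
  cat("Agent parameters (", x$kind, ")\n", sep = "")
  free <- c("alpha", "eta", "omega", "amp_mf_to_mb", "amp_mb_to_mf", "beta")
  cat(paste(sprintf("  %-13s %.4g", free, unlist(x[free])), collapse = "\n"),
      "\n")
  invisible(x)
}

.variant_code <- function(variant) {
  switch(variant, arbitrating = 0L, random = 0L, mf_only = 1L, mb_only = 2L,
         stop("unknown model variant"))
}

.par_list <- function(params, variant) {
  list(alpha = params$alpha, eta = params$eta, omega = params$omega,
       amp_mf_to_mb = params$amp_mf_to_mb, amp_mb_to_mf = params$amp_mb_to_mf,
       beta = params$beta, B = params$B, bias_mf = params$bias_mf,
       omega_max = params$omega_max, p_mb0 = params$p_mb0,
       zspe0 = params$zspe0, miss_prob = params$miss_prob,
       variant = .variant_code(variant))
}

.t_init_matrix <- function(params) {
  if (is.null(params$t_init)) matrix(0.5, 5, 2) else unname(params$t_init)
}

.encode_plan <- function(plan) {
  cbind(
    condition = as.integer(plan$condition == "specific"),
    uncertainty = as.integer(plan$uncertainty == "high"),
    goal = unname(.colour_codes[plan$goal]),
    training = as.integer(plan$session == "training")
  )
}

.encode_observed <- function(trials, env) {
  code <- env$enc$state_code
  tr <- env$transitions
  key1 <- paste("S0", trials$a0)
  ok1 <- trials$s1 == tr$likely[match(key1, paste(tr$state, tr$action))] |
    trials$s1 == tr$unlikely[match(key1, paste(tr$state, tr$action))]
  key2 <- paste(trials$s1, trials$a1)
  ok2 <- trials$s2 == tr$likely[match(key2, paste(tr$state, tr$action))] |
    trials$s2 == tr$unlikely[match(key2, paste(tr$state, tr$action))]
  if (anyNA(c(ok1, ok2)) || !all(ok1, ok2))
    stop("trial log contains transitions the environment cannot produce")
  cbind(
    a0 = match(trials$a0, env$actions) - 1L,
    s1 = unname(code[trials$s1]),
    a1 = match(trials$a1, env$actions) - 1L,
    s2 = unname(code[trials$s2]),
    excluded = as.integer(trials$excluded)
  )
}

.assemble_trials <- function(plan, out, env) {
  plan <- as.data.frame(plan)
  map <- env$outcome_map
  s1 <- env$states[out[, 2] + 1L]
  s2 <- env$states[out[, 4] + 1L]
  plan$s0 <- "S0"
  plan$a0 <- env$actions[out[, 1] + 1L]
  plan$s1 <- s1
  plan$a1 <- env$actions[out[, 3] + 1L]
  plan$s2 <- s2
  plan$outcome_colour <- map$colour[match(s2, map$state)]
  plan$outcome_value <- out[, 5]
  plan$shocks <- out[, 6]
  plan$excluded <- out[, 7] == 1L
  plan
}

.assemble_trace <- function(tr) {
  tr <- as.data.frame(tr)
  names(tr) <- .trace_cols
  tr$trial <- seq_len(nrow(tr))
  tr[, c("trial", .trace_cols)]
}

#' Simulate one agent through a session plan
#'
#' Runs a single agent trial by trial: outcome devaluation for the current
#' goal, softmax first-stage choice on the integrated values, stochastic
#' transition, transition-model (SPE) update and replanning, second-stage
#' choice, outcome delivery under the goal rule, SARSA (OPE) updates,
#' reliability updates after every prediction error and one
#' controller-weight update per trial. During the training session no
#' shocks are delivered; learning is driven by the displayed coin
#' magnitudes.
#'
#' @param env An `avoid_env` environment.
#' @param params An `agent_parameters` object; its `kind` selects the agent.
#' @param plan A `session_plan` (see [generate_session_plan()]).
#' @param seed Optional integer seed; identical seeds give byte-identical
#'   trial logs and traces.
#' @return A list of class `avoid_sim` with `trials` (the behavioural trial
#'   log) and `trace` (per-trial latent variables: prediction errors,
#'   `Omega`, reliabilities, the weight `p_mb` that governed the trial's
#'   choices, per-stage choice probabilities and the faced value-table
#'   rows). The ideal agent carries no latent trace.
#' @examples
#' env <- build_environment()
#' plan <- generate_session_plan(seed = 1)
#' sim <- simulate_agent(env, agent_parameters(), plan, seed = 1)
#' head(sim$trials)
#' @export
simulate_agent <- function(env, params, plan, seed = NULL) {
  stopifnot(inherits(env, "avoid_env"), inherits(params, "agent_parameters"))
  if (!is.null(seed)) set.seed(seed)
  if (params$kind == "ideal")
    return(.simulate_ideal(env, plan, params))
  if (params$kind == "random") params$beta <- 0
  res <- .run_engine(env$enc$succ, env$enc$out_value, env$enc$out_colour,
                     unname(env$p_likely), .par_list(params, params$kind),
                     .encode_plan(plan), NULL, TRUE, FALSE,
                     .t_init_matrix(params))
  structure(
    list(trials = .assemble_trials(plan, res$trials, env),
         trace = .assemble_trace(res$trace), params = params, seed = seed),
    class = "avoid_sim"
  )
}

#' @export
print.avoid_sim <- function(x, ...) {
  tr <- x$trials
  cat("Simulated agent (", x$params$kind, "): ", nrow(tr), " trials, ",
      length(unique(tr$block[tr$session != "training"])),
      " experimental blocks\n", sep = "")
  invisible(x)
}

.simulate_ideal <- function(env, plan, params) {
  n <- nrow(plan)
  pol_cache <- new.env(parent = emptyenv())
  a0 <- a1 <- s1 <- s2 <- character(n)
  for (i in seq_len(n)) {
    key <- paste(plan$condition[i], plan$uncertainty[i], plan$goal[i])
    pol <- pol_cache[[key]]
    if (is.null(pol)) {
      pol <- ideal_agent_policy(env, plan$condition[i], plan$uncertainty[i],
                                plan$goal[i])
      pol_cache[[key]] <- pol
    }
    a0[i] <- pol[["S0"]]
    s1[i] <- sample_transition(env, "S0", a0[i], plan$uncertainty[i])
    a1[i] <- pol[[s1[i]]]
    s2[i] <- sample_transition(env, s1[i], a1[i], plan$uncertainty[i])
  }
  map <- env$outcome_map
  face <- map$shocks[match(s2, map$state)]
  colour <- map$colour[match(s2, map$state)]
  shocks <- deliver_outcome(colour, face,
                            plan$condition,
                            ifelse(plan$condition == "specific",
                                   plan$goal, "red"))
  shocks[plan$session == "training"] <- 0L
  trials <- as.data.frame(plan)
  trials$s0 <- "S0"
  trials$a0 <- a0
  trials$s1 <- s1
  trials$a1 <- a1
  trials$s2 <- s2
  trials$outcome_colour <- colour
  trials$outcome_value <- face
  trials$shocks <- as.integer(shocks)
  trials$excluded <- FALSE
  structure(list(trials = trials, trace = NULL, params = params, seed = NULL),
            class = "avoid_sim")
}

#' Expectimax-optimal policy under the true task
#'
#' Computes the ideal agent's action at every choice state by exact
#' expectimax over the two-level tree, using the true transition
#' probabilities of the given uncertainty level and the goal-devalued
#' outcome values. Ties are broken by fixed action order (`L` before `R`).
#'
#' @param env An `avoid_env` environment.
#' @param condition `"flexible"` or `"specific"`.
#' @param uncertainty `"low"` or `"high"`.
#' @param goal_colour Goal colour of the trial (specific condition).
#' @return Named character vector of optimal actions over the five choice
#'   states.
#' @examples
#' env <- build_environment()
#' ideal_agent_policy(env, "flexible", "low")[["S0"]] # "R"
#' @export
ideal_agent_policy <- function(env, condition, uncertainty = c("low", "high"),
                               goal_colour = "white") {
  stopifnot(inherits(env, "avoid_env"))
  uncertainty <- match.arg(uncertainty)
  p <- env$p_likely[[uncertainty]]
  map <- env$outcome_map
  if (condition == "specific") {
    if (!goal_colour %in% c("red", "yellow", "blue"))
      stop("specific-condition goal colour must be red, yellow or blue")
    term <- setNames(ifelse(map$colour == goal_colour, -map$shocks, -4),
                     map$state)
  } else {
    term <- setNames(-map$shocks, map$state)
  }
  tr <- env$transitions
  q <- matrix(NA_real_, 5, 2, dimnames = list(env$choice_states, env$actions))
  second <- tr[tr$state != "S0", ]
  for (i in seq_len(nrow(second)))
    q[second$state[i], second$action[i]] <-
      p * term[[second$likely[i]]] + (1 - p) * term[[second$unlikely[i]]]
  first <- tr[tr$state == "S0", ]
  for (i in seq_len(nrow(first)))
    q["S0", first$action[i]] <-
      p * max(q[first$likely[i], ]) + (1 - p) * max(q[first$unlikely[i], ])
  apply(q, 1, function(row) env$actions[which.max(row)])
}

#' Simulate a cohort of agents
#'
#' Draws per-subject parameters from a sampler, generates an independent
#' session plan and trial log per subject (child seeds derived
#' deterministically from the master seed) and keeps the true parameters
#' for recovery studies.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param param_sampler Either `NULL` (every subject uses
#'   [agent_parameters()] defaults) or a function `f(n)` returning a data
#'   frame with columns `alpha`, `eta`, `omega`, `amp_mf_to_mb`,
#'   `amp_mb_to_mf`, `beta` (one row per subject).
#' @param config Task configuration for the session plans.
#' @param seed Master seed.
#' @param kind Agent kind passed to [agent_parameters()].
#' @return A list of class `avoid_cohort`; each element holds `subject`,
#'   `params` (the true generating parameters), `trials`, `trace`, `seed`.
#' @export
simulate_cohort <- function(n_subjects, param_sampler = NULL,
                            config = default_task_config(), seed = 1,
                            kind = "arbitrating") {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, 2L * n_subjects)
  par_tab <- if (is.null(param_sampler)) NULL else param_sampler(n_subjects)
  env <- build_environment(config)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    if (is.null(par_tab)) {
      params <- agent_parameters(kind = kind)
    } else {
      params <- agent_parameters(
        alpha = par_tab$alpha[i], eta = par_tab$eta[i],
        omega = par_tab$omega[i],
        amp_mf_to_mb = par_tab$amp_mf_to_mb[i],
        amp_mb_to_mf = par_tab$amp_mb_to_mf[i],
        beta = par_tab$beta[i], kind = kind
      )
    }
    plan <- generate_session_plan(config, seed = child[2L * i - 1L])
    sim <- simulate_agent(env, params, plan, seed = child[2L * i])
    sim$trials$subject <- i
    out[[i]] <- list(subject = i, params = params, trials = sim$trials,
                     trace = sim$trace, seed = child[2L * i])
  }
  structure(out, class = "avoid_cohort")
}

#' Teacher-forced replay of a trial log
#'
#' Walks the model along the observed choices and outcomes of a trial log
#' (the exact code path used by simulation), returning the per-trial latent
#' trace and the negative log-likelihood of the observed choices.
#'
#' @param trials A trial log as produced by [simulate_agent()] (or read by
#'   [read_trial_log()]).
#' @param params An `agent_parameters` object.
#' @param env An `avoid_env` environment.
#' @param variant Weighting rule: `"arbitrating"` (dynamic `p_mb`),
#'   `"mf_only"` (`p_mb = 0`) or `"mb_only"` (`p_mb = 1`).
#' @param include_training Count training-session choices in the
#'   log-likelihood? Training is always replayed for learning either way.
#' @return A list of class `avoid_replay` with `trace`, `nll` and
#'   `n_choices`.
#' @export
replay_agent <- function(trials, params, env,
                         variant = c("arbitrating", "mf_only", "mb_only"),
                         include_training = FALSE) {
  stopifnot(inherits(env, "avoid_env"), inherits(params, "agent_parameters"))
  variant <- match.arg(variant)
  res <- .run_engine(env$enc$succ, env$enc$out_value, env$enc$out_colour,
                     unname(env$p_likely), .par_list(params, variant),
                     .encode_plan(trials), .encode_observed(trials, env),
                     FALSE, include_training, .t_init_matrix(params))
  structure(list(trace = .assemble_trace(res$trace), nll = res$nll,
                 n_choices = res$n_choices, n_excluded = res$n_excluded,
                 variant = variant),
            class = "avoid_replay")
}
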