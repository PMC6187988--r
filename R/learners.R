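#' Initialise the model-free SARSA learner
#'
#' The model-free system holds a table of state-action values over the five
#' choice states, learned directly from experienced (signed) outcomes by
#' temporal-difference updates. Shocks enter with negative sign, so both
#' systems maximise value and avoidance is maximisation of negative pain.
#' Values start at zero (the least-informative initialisation); in a full
#' simulated experiment the 100-trial training session then shapes them
#' before the experimental sessions begin.
#'
#' @param env An `avoid_env` environment.
#' @param alpha Learning rate in (0, 1], shared with the model-based
#'   transition learner.
#' @return A list of class `mf_state` with elements `q` (5 x 2 value matrix)
#'   and `alpha`.
#' @export
mf_init <- function(env, alpha = 0.5) {
  stopifnot(inherits(env, "avoid_env"))
  .check_alpha(alpha)
  q <- matrix(0, nrow = 5, ncol = 2,
              dimnames = list(env$choice_states, env$actions))
  structure(list(q = q, alpha = alpha), class = "mf_state")
}

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
}

#' One SARSA update of the model-free values
#'
#' Applies the outcome-prediction-error update
#' `OPE = r + Q(s', a') - Q(s, a)`; `Q(s, a) <- Q(s, a) + alpha * OPE`.
#' For the first-stage transition no outcome has occurred yet (`r = 0`) and
#' the value bootstraps from the chosen second-stage action (on-policy). At
#' the terminal transition the successor term is zero and `r` is the signed
#' outcome (minus the delivered shocks).
#'
#' @param mf An `mf_state`.
#' @param s,a The updated choice state and action.
#' @param r Signed immediate outcome (0 at the first stage, `-shocks` at the
#'   outcome).
#' @param s_next,a_next The successor choice state and the action taken
#'   there, or `NULL` for a terminal transition.
#' @return A list with the updated `mf` and the prediction error `ope`.
#' @examples
#' env <- build_environment()
#' mf <- mf_init(env, alpha = 0.5)
#' mf_update(mf, "I3", "R", r = -4)$ope # -4
#' @export
mf_update <- function(mf, s, a, r, s_next = NULL, a_next = NULL) {
  stopifnot(inherits(mf, "mf_state"))
  .check_alpha(mf$alpha)
  if (!s %in% rownames(mf$q) || !a %in% colnames(mf$q))
    stop("unknown (state, action) pair")
  boot <- 0
  if (!is.null(s_next) && s_next %in% rownames(mf$q)) {
    if (is.null(a_next)) stop("a_next required when s_next is a choice state")
    boot <- mf$q[s_next, a_next]
  }
  ope <- r + boot - mf$q[s, a]
  mf$q[s, a] <- mf$q[s, a] + mf$alpha * ope
  list(mf = mf, ope = ope)
}

#' Initialise the model-based (FORWARD) learner
#'
#' The model-based system learns the state-transition matrix `T(s, a, s')`
#' from state prediction errors and computes its values by exact backward
#' induction over the two-level tree, using the current (possibly devalued)
#' terminal values of the outcome states. `T` starts uniform over the two
#' configured successors of every pair; terminal values start at the
#' flexible-condition map (minus the coin face values).
#'
#' @param env An `avoid_env` environment.
#' @param alpha Learning rate in (0, 1] for the transition update (shared
#'   with the model-free system).
#' @return A list of class `mb_state` with elements `p_likely` (5 x 2 matrix
#'   of learned probabilities of the designated likely successor), `term`
#'   (named terminal values of the outcome states), `q` (5 x 2 model-based
#'   values) and `alpha`.
#' @export
mb_init <- function(env, alpha = 0.5) {
  stopifnot(inherits(env, "avoid_env"))
  .check_alpha(alpha)
  p <- matrix(0.5, nrow = 5, ncol = 2,
              dimnames = list(env$choice_states, env$actions))
  term <- setNames(-as.numeric(env$outcome_map$shocks), env$outcome_states)
  mb <- structure(list(p_likely = p, term = term, q = NULL, alpha = alpha,
                       env = env), class = "mb_state")
  mb_compute_values(mb)
}

#' Transition-probability table of a model-based learner
#'
#' @param mb An `mb_state`.
#' @return Data frame with one row per (state, action, successor) and the
#'   learned probability; rows for a pair sum to 1.
#' @export
mb_transition_table <- function(mb) {
  stopifnot(inherits(mb, "mb_state"))
  tr <- mb$env$transitions
  out <- rbind(
    data.frame(state = tr$state, action = tr$action, successor = tr$likely,
               prob = mb$p_likely[cbind(tr$state, tr$action)],
               stringsAsFactors = FALSE),
    data.frame(state = tr$state, action = tr$action, successor = tr$unlikely,
               prob = 1 - mb$p_likely[cbind(tr$state, tr$action)],
               stringsAsFactors = FALSE)
  )
  out[order(match(out$state, .choice_states), out$action), , drop = FALSE]
}

#' Update the learned transition model from an observed transition
#'
#' Applies the state-prediction-error update `SPE = 1 - T(s, a, s_obs)`;
#' `T(s, a, s_obs) <- T(s, a, s_obs) + alpha * SPE`, with the remaining
#' successor of the pair rescaled so the row still sums to one.
#'
#' @param mb An `mb_state`.
#' @param s,a The choice state left and the action taken.
#' @param s_obs The successor state actually observed; must be one of the
#'   two configured successors of `(s, a)`.
#' @return A list with the updated `mb` (values recomputed) and the `spe`.
#' @export
mb_update_transition <- function(mb, s, a, s_obs) {
  stopifnot(inherits(mb, "mb_state"))
  tr <- mb$env$transitions
  row <- tr[tr$state == s & tr$action == a, ]
  if (nrow(row) != 1L) stop("unknown (state, action) pair")
  if (!s_obs %in% c(row$likely, row$unlikely))
    stop("observed successor is not configured for this (state, action) pair")
  p <- mb$p_likely[s, a]
  if (s_obs == row$likely) {
    spe <- 1 - p
    mb$p_likely[s, a] <- p + mb$alpha * spe
  } else {
    spe <- p
    mb$p_likely[s, a] <- p - mb$alpha * spe
  }
  mb <- mb_compute_values(mb)
  list(mb = mb, spe = spe)
}

#' Recompute model-based values by backward induction
#'
#' `Q_MB(s, a) = sum_s' T(s, a, s') * (r(s') + max_a' Q_MB(s', a'))`:
#' second-stage values are expected terminal values; the initial state takes
#' the expectation of the max over second-stage actions.
#'
#' @param mb An `mb_state` with terminal values populated.
#' @return The `mb_state` with its `q` table updated.
#' @export
mb_compute_values <- function(mb) {
  stopifnot(inherits(mb, "mb_state"))
  if (any(!is.finite(mb$term)))
    stop("terminal values must be populated for all outcome states")
  tr <- mb$env$transitions
  q <- matrix(NA_real_, 5, 2, dimnames = dimnames(mb$p_likely))
  second <- tr[tr$state != "S0", ]
  for (i in seq_len(nrow(second))) {
    p <- mb$p_likely[second$state[i], second$action[i]]
    q[second$state[i], second$action[i]] <-
      p * mb$term[[second$likely[i]]] + (1 - p) * mb$term[[second$unlikely[i]]]
  }
  first <- tr[tr$state == "S0", ]
  for (i in seq_len(nrow(first))) {
    p <- mb$p_likely["S0", first$action[i]]
    v1 <- max(q[first$likely[i], ])
    v2 <- max(q[first$unlikely[i], ])
    q["S0", first$action[i]] <- p * v1 + (1 - p) * v2
  }
  mb$q <- q
  mb
}

#' Devalue outcome states according to the current goal
#'
#' Backward planning on a goal change: in the specific-goal condition only
#' the coin matching the goal colour keeps its (negative) face value and all
#' other outcome states are set to the devalued -4; in the flexible
#' condition every coin keeps its face value. Model-based values are
#' recomputed afterwards.
#'
#' @param mb An `mb_state`.
#' @param condition `"flexible"` or `"specific"`.
#' @param goal_colour Goal colour (`"red"`, `"yellow"` or `"blue"` in the
#'   specific condition; ignored in flexible).
#' @return The updated `mb_state`.
#' @examples
#' env <- build_environment()
#' mb <- mb_init(env)
#' devalue_outcomes(mb, "specific", "red")$term # 0 -4 -4 -4
#' @export
devalue_outcomes <- function(mb, condition, goal_colour = "white") {
  stopifnot(inherits(mb, "mb_state"))
  if (!condition %in% c("flexible", "specific"))
    stop("condition must be 'flexible' or 'specific'")
  map <- mb$env$outcome_map
  if (condition == "specific") {
    if (!goal_colour %in% c("red", "yellow", "blue"))
      stop("specific-condition goal colour must be red, yellow or blue")
    vals <- ifelse(map$colour == goal_colour, -map$shocks, -4)
  } else {
    vals <- -map$shocks
  }
  mb$term <- setNames(as.numeric(vals), map$state)
  mb_compute_values(mb)
}
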