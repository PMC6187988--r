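#' Default configuration of the two-step avoidance task
#'
#' Returns the task configuration used throughout: one initial choice state
#' (`S0`), four intermediate choice states (`I1`-`I4`), four outcome states
#' (`O1`-`O4`) shown as coloured coins carrying 0, 1, 2 or 4 electric shocks.
#' Transition probabilities to the two configured successors of every
#' (choice state, action) pair are 0.9/0.1 in the low-uncertainty condition
#' and 0.5/0.5 in high. The default successor layout is chosen so that in
#' the flexible-goal condition the optimal first-stage action (`R`) is the
#' same under both uncertainty levels while the optimal second-stage action
#' at the likely intermediate state flips between them.
#'
#' @return A named list with elements `coins` (outcome state, colour, shock
#'   count), `transitions` (likely/unlikely successor per state and action),
#'   `p_likely` (probability of the likely successor per uncertainty level),
#'   block scheduling settings (`blocks_per_cell`, `n_sessions`,
#'   `trials_low`, `trials_high`, `training_trials`) and the `goal_colours`
#'   eligible in the specific-goal condition.
#' @seealso [build_environment()], [generate_session_plan()]
#' @export
default_task_config <- function() {
  list(
    coins = data.frame(
      state = c("O1", "O2", "O3", "O4"),
      colour = c("red", "yellow", "blue", "grey"),
      shocks = c(0, 1, 2, 4),
      stringsAsFactors = FALSE
    ),
    transitions = data.frame(
      state    = c("S0", "S0", "I1", "I1", "I2", "I2", "I3", "I3", "I4", "I4"),
      action   = c("L", "R", "L", "R", "L", "R", "L", "R", "L", "R"),
      likely   = c("I1", "I3", "O2", "O3", "O3", "O1", "O3", "O1", "O4", "O2"),
      unlikely = c("I2", "I4", "O4", "O4", "O2", "O4", "O2", "O4", "O1", "O3"),
      stringsAsFactors = FALSE
    ),
    p_likely = c(low = 0.9, high = 0.5),
    blocks_per_cell = 12L,
    n_sessions = 2L,
    trials_low = c(3L, 5L),
    trials_high = c(5L, 7L),
    training_trials = 100L,
    goal_colours = c("red", "yellow", "blue")
  )
}

#' Build and validate the task environment
#'
#' Assembles the state tree, transition tables and outcome map from a task
#' configuration, checking the structural invariants of the design: nine
#' distinct states, two actions per choice state, transition probability
#' vectors summing to one and equal to \{0.9, 0.1\} (low uncertainty) or
#' \{0.5, 0.5\} (high), shock magnitudes \{0, 1, 2, 4\} with the 0-shock
#' coin red and the 4-shock coin grey.
#'
#' @param config A task configuration list, as returned by
#'   [default_task_config()] or [read_task_config()].
#' @return An object of class `avoid_env`.
#' @examples
#' env <- build_environment()
#' env
#' @export
build_environment <- function(config = default_task_config()) {
  coins <- as.data.frame(config$coins, stringsAsFactors = FALSE)
  trans <- as.data.frame(config$transitions, stringsAsFactors = FALSE)

  states <- c("S0", paste0("I", 1:4), coins$state)
  if (anyDuplicated(states) > 0)
    stop("duplicate state identifiers in configuration")
  if (!setequal(coins$state, .outcome_states) || nrow(coins) != 4L)
    stop("outcome mapping must cover exactly the four outcome states")
  if (!setequal(coins$colour, .coin_colours))
    stop("coin colours must be exactly red, yellow, blue and grey")
  if (!setequal(coins$shocks, c(0, 1, 2, 4)))
    stop("shock magnitudes must be exactly {0, 1, 2, 4}")
  if (coins$colour[coins$shocks == 0] != "red")
    stop("the 0-shock coin must be red")
  if (coins$colour[coins$shocks == 4] != "grey")
    stop("the 4-shock coin must be grey")

  key <- paste(trans$state, trans$action)
  need <- as.vector(outer(.choice_states, .actions, paste))
  if (!setequal(key, need) || anyDuplicated(key) > 0)
    stop("transitions must list every (choice state, action) pair exactly once")
  first <- trans$state == "S0"
  if (!all(trans$likely[first] %in% .states[2:5]) ||
      !all(trans$unlikely[first] %in% .states[2:5]))
    stop("first-stage successors must be intermediate states")
  if (!all(trans$likely[!first] %in% .outcome_states) ||
      !all(trans$unlikely[!first] %in% .outcome_states))
    stop("second-stage successors must be outcome states")
  if (any(trans$likely == trans$unlikely))
    stop("the two successors of a (state, action) pair must differ")

  p <- lapply(config$p_likely, function(x) {
    v <- if (length(x) == 1L) c(x, 1 - x) else as.numeric(x)
    if (abs(sum(v) - 1) > 1e-12)
      stop("transition probability vector does not sum to 1")
    v
  })
  if (!isTRUE(all.equal(sort(p$low), c(0.1, 0.9), tolerance = 1e-12)))
    stop("low-uncertainty transition probabilities must be {0.9, 0.1}")
  if (!isTRUE(all.equal(p$high, c(0.5, 0.5), tolerance = 1e-12)))
    stop("high-uncertainty transition probabilities must be {0.5, 0.5}")

  state_code <- setNames(seq_along(.states) - 1L, .states)
  ord <- order(match(trans$state, .choice_states), match(trans$action, .actions))
  trans <- trans[ord, , drop = FALSE]
  rownames(trans) <- NULL
  succ <- integer(20)
  for (i in seq_len(nrow(trans))) {
    s <- state_code[[trans$state[i]]]
    a <- match(trans$action[i], .actions) - 1L
    succ[(s * 2L + a) * 2L + 1L] <- state_code[[trans$likely[i]]]
    succ[(s * 2L + a) * 2L + 2L] <- state_code[[trans$unlikely[i]]]
  }
  coins <- coins[match(.outcome_states, coins$state), , drop = FALSE]
  rownames(coins) <- NULL

  structure(
    list(
      states = .states,
      choice_states = .choice_states,
      outcome_states = .outcome_states,
      actions = .actions,
      transitions = trans,
      outcome_map = coins,
      p_likely = c(low = max(p$low), high = max(p$high)),
      config = config,
      enc = list(
        succ = succ,
        out_value = as.numeric(coins$shocks),
        out_colour = unname(.colour_codes[coins$colour]),
        state_code = state_code
      )
    ),
    class = "avoid_env"
  )
}

#' @export
print.avoid_env <- function(x, ...) {
  cat("Two-step avoidance task environment\n")
  cat("  states:", length(x$states), "(1 initial, 4 intermediate, 4 outcome)\n")
  cat("  p(likely successor): low =", x$p_likely[["low"]],
      ", high =", x$p_likely[["high"]], "\n")
  cat("  outcome coins:",
      paste(sprintf("%s=%d", x$outcome_map$colour, x$outcome_map$shocks),
            collapse = ", "), "\n")
  invisible(x)
}

#' Sample a state transition
#'
#' Draws successor states for a (choice state, action) pair under a given
#' uncertainty level, using the true task transition probabilities and R's
#' random number stream (so results are reproducible under [set.seed()]).
#'
#' @param env An `avoid_env` environment.
#' @param state A choice state (`"S0"` or `"I1"`-`"I4"`).
#' @param action `"L"` or `"R"`.
#' @param uncertainty `"low"` (0.9/0.1) or `"high"` (0.5/0.5).
#' @param n Number of independent draws.
#' @return Character vector of successor states, length `n`.
#' @examples
#' env <- build_environment()
#' set.seed(1)
#' table(sample_transition(env, "S0", "L", "low", n = 1000))
#' @export
sample_transition <- function(env, state, action, uncertainty = c("low", "high"),
                              n = 1L) {
  stopifnot(inherits(env, "avoid_env"))
  uncertainty <- match.arg(uncertainty)
  if (!state %in% env$choice_states)
    stop("transitions can only be sampled from a choice state")
  if (!action %in% env$actions) stop("unknown action")
  row <- env$transitions[env$transitions$state == state &
                           env$transitions$action == action, ]
  p <- env$p_likely[[uncertainty]]
  ifelse(runif(n) < p, row$likely, row$unlikely)
}

#' Apply the goal-devaluation rule to an acquired coin
#'
#' In the flexible-goal condition every coin retains its face value. In the
#' specific-goal condition only the coin matching the goal colour keeps its
#' value; any mismatching coin delivers the default maximum of 4 shocks.
#'
#' @param coin_colour Colour of the acquired coin (`"red"`, `"yellow"`,
#'   `"blue"` or `"grey"`). Vectorised.
#' @param coin_value Face value of the coin in shocks (0, 1, 2 or 4).
#' @param condition `"flexible"` or `"specific"`.
#' @param goal_colour Goal colour of the trial; must be `"red"`, `"yellow"`
#'   or `"blue"` in the specific condition (never grey or white).
#' @return Numeric vector of shocks actually delivered.
#' @examples
#' deliver_outcome("red", 0, "specific", "red")  # 0
#' deliver_outcome("red", 0, "specific", "blue") # 4
#' deliver_outcome("yellow", 2, "flexible", "white") # 2
#' @export
deliver_outcome <- function(coin_colour, coin_value, condition, goal_colour) {
  n <- max(length(coin_colour), length(coin_value), length(condition),
           length(goal_colour))
  coin_colour <- rep_len(coin_colour, n)
  coin_value <- rep_len(coin_value, n)
  condition <- rep_len(condition, n)
  goal_colour <- rep_len(goal_colour, n)
  if (!all(condition %in% c("flexible", "specific")))
    stop("condition must be 'flexible' or 'specific'")
  if (!all(coin_colour %in% .coin_colours)) stop("unknown coin colour")
  if (!all(coin_value %in% c(0, 1, 2, 4))) stop("coin value must be 0, 1, 2 or 4")
  spec <- condition == "specific"
  if (any(!goal_colour[spec] %in% c("red", "yellow", "blue")))
    stop("specific-condition goal colour must be red, yellow or blue")
  out <- coin_value
  out[spec & coin_colour != goal_colour] <- 4
  out
}

#' Generate a randomised session plan
#'
#' Builds the trial schedule of a full experiment: an optional 100-trial
#' training session (flexible goal, high-uncertainty transitions, no shock
#' delivery), followed by two experimental sessions that together hold 12
#' blocks of each condition cell (flexible/specific crossed with low/high
#' uncertainty; 48 blocks in total), randomly interleaved within session.
#' Low-uncertainty blocks run 3-5 trials, high-uncertainty blocks 5-7. In
#' specific-goal blocks the goal colour is resampled uniformly from
#' \{red, yellow, blue\} on every trial.
#'
#' @param config Task configuration (see [default_task_config()]).
#' @param seed Optional integer seed for reproducible plans.
#' @param include_training Include the training session at the start?
#' @return A data frame of class `session_plan`, one row per trial, with
#'   columns `session`, `block`, `block_in_session`, `trial_in_block`,
#'   `condition`, `uncertainty`, `goal` and global `trial`.
#' @examples
#' plan <- generate_session_plan(seed = 1)
#' length(unique(plan$block[plan$session != "training"])) # 48
#' @export
generate_session_plan <- function(config = default_task_config(), seed = NULL,
                                  include_training = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  bpc <- as.integer(config$blocks_per_cell)
  nses <- as.integer(config$n_sessions)
  if (bpc %% nses != 0L)
    stop("blocks per condition cell must divide evenly over sessions")
  cells <- expand.grid(condition = c("flexible", "specific"),
                       uncertainty = c("low", "high"),
                       stringsAsFactors = FALSE)

  rows <- list()
  if (include_training) {
    ntr <- as.integer(config$training_trials)
    rows[[1]] <- data.frame(
      session = "training", block = 0L, block_in_session = 0L,
      trial_in_block = seq_len(ntr), condition = "flexible",
      uncertainty = "high", goal = "white", stringsAsFactors = FALSE
    )
  }

  blk <- 0L
  for (ses in seq_len(nses)) {
    idx <- rep(seq_len(nrow(cells)), each = bpc %/% nses)
    idx <- sample(idx)
    for (j in seq_along(idx)) {
      blk <- blk + 1L
      cell <- cells[idx[j], ]
      rng <- if (cell$uncertainty == "low") config$trials_low else config$trials_high
      nt <- sample(seq.int(rng[1], rng[2]), 1L)
      goals <- if (cell$condition == "specific")
        sample(config$goal_colours, nt, replace = TRUE)
      else rep("white", nt)
      rows[[length(rows) + 1L]] <- data.frame(
        session = paste0("exp", ses), block = blk, block_in_session = j,
        trial_in_block = seq_len(nt), condition = cell$condition,
        uncertainty = cell$uncertainty, goal = goals, stringsAsFactors = FALSE
      )
    }
  }
  plan <- do.call(rbind, rows)
  plan$trial <- seq_len(nrow(plan))
  rownames(plan) <- NULL
  class(plan) <- c("session_plan", "data.frame")
  plan
}
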