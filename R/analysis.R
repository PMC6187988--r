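#' Exact outcome distribution of a policy by path enumeration
#'
#' Enumerates all first-action / transition / second-action / outcome paths
#' of the two-step tree and returns the exact distribution of delivered
#' shocks for a deterministic policy (or the uniform random policy), under
#' the true transition probabilities and the goal-devaluation rule. Used
#' for the closed-form random-agent and ideal-agent baselines.
#'
#' @param env An `avoid_env` environment.
#' @param condition `"flexible"` or `"specific"`.
#' @param uncertainty `"low"` or `"high"`.
#' @param goal_colour Goal colour (specific condition).
#' @param policy Named action vector over the choice states (as returned by
#'   [ideal_agent_policy()]) or `NULL` for uniform random choice.
#' @param success_rule Definition of a successful trial: `"zero"` (0 shocks
#'   delivered, the default) or `"lt4"` (anything less than the 4-shock
#'   maximum).
#' @return Named numeric vector: probability of delivering 0, 1, 2 and 4
#'   shocks (sums to one), with attributes `e_shocks` (expected shocks) and
#'   `p_success` (probability of a successful trial).
#' @export
outcome_distribution <- function(env, condition,
                                 uncertainty = c("low", "high"),
                                 goal_colour = "white", policy = NULL,
                                 success_rule = c("zero", "lt4")) {
  success_rule <- match.arg(success_rule)
  stopifnot(inherits(env, "avoid_env"))
  uncertainty <- match.arg(uncertainty)
  p <- env$p_likely[[uncertainty]]
  tr <- env$transitions
  map <- env$outcome_map
  dist <- setNames(numeric(4), c("0", "1", "2", "4"))
  pa <- function(state, action) {
    if (is.null(policy)) 0.5 else as.numeric(policy[[state]] == action)
  }
  for (a0 in env$actions) {
    row0 <- tr[tr$state == "S0" & tr$action == a0, ]
    for (slot1 in 1:2) {
      s1 <- if (slot1 == 1) row0$likely else row0$unlikely
      p1 <- if (slot1 == 1) p else 1 - p
      for (a1 in env$actions) {
        row1 <- tr[tr$state == s1 & tr$action == a1, ]
        for (slot2 in 1:2) {
          s2 <- if (slot2 == 1) row1$likely else row1$unlikely
          p2 <- if (slot2 == 1) p else 1 - p
          idx <- match(s2, map$state)
          shocks <- deliver_outcome(map$colour[idx], map$shocks[idx],
                                    condition,
                                    if (condition == "specific") goal_colour
                                    else "white")
          prob <- pa("S0", a0) * p1 * pa(s1, a1) * p2
          dist[as.character(shocks)] <- dist[as.character(shocks)] + prob
        }
      }
    }
  }
  structure(dist,
            e_shocks = sum(dist * c(0, 1, 2, 4)),
            p_success = if (success_rule == "zero") unname(dist["0"])
                        else unname(1 - dist["4"]))
}

.cell_baseline <- function(env, condition, uncertainty, ideal = FALSE,
                           success_rule = "zero") {
  goals <- if (condition == "specific") c("red", "yellow", "blue") else "white"
  e <- s <- 0
  for (g in goals) {
    pol <- if (ideal) ideal_agent_policy(env, condition, uncertainty, g)
           else NULL
    d <- outcome_distribution(env, condition, uncertainty, g, pol,
                              success_rule)
    e <- e + attr(d, "e_shocks") / length(goals)
    s <- s + attr(d, "p_success") / length(goals)
  }
  c(shocks_avoided = 4 - e, success_rate = s)
}

.optimal_actions <- function(env, trials) {
  pol_cache <- new.env(parent = emptyenv())
  n <- nrow(trials)
  opt0 <- opt1 <- character(n)
  for (i in seq_len(n)) {
    key <- paste(trials$condition[i], trials$uncertainty[i], trials$goal[i])
    pol <- pol_cache[[key]]
    if (is.null(pol)) {
      pol <- ideal_agent_policy(env, trials$condition[i],
                                trials$uncertainty[i], trials$goal[i])
      pol_cache[[key]] <- pol
    }
    opt0[i] <- pol[["S0"]]
    opt1[i] <- pol[[trials$s1[i]]]
  }
  data.frame(opt_a0 = opt0, opt_a1 = opt1, stringsAsFactors = FALSE)
}

#' Behavioural performance summaries by condition cell
#'
#' Computes, for every condition-by-uncertainty cell of the experimental
#' sessions, the mean shocks avoided per trial (out of 4), the success rate
#' (proportion of 0-shock trials) and the proportion of optimal choices
#' (overall and per stage, judged against the expectimax ideal policy for
#' the trial's goal; the stage-two judgement is conditional on the realised
#' intermediate state). Training-session and excluded (penalising) trials
#' are dropped. Means and standard errors are taken across subjects, and
#' exact random-agent and ideal-agent baselines computed by path
#' enumeration are attached.
#'
#' @param datasets A trial log, a list of trial logs, or an `avoid_cohort`.
#' @param env An `avoid_env` environment.
#' @param success_rule Definition of a successful trial: `"zero"` (0 shocks
#'   delivered, the default) or `"lt4"` (fewer than the 4-shock maximum).
#' @return Data frame of class `avoid_summary`: one row per cell and
#'   metric, with columns `condition`, `uncertainty`, `metric`, `mean`,
#'   `sem`, `random`, `ideal`.
#' @export
performance_metrics <- function(datasets, env,
                                success_rule = c("zero", "lt4")) {
  success_rule <- match.arg(success_rule)
  tl <- .as_trial_list(datasets)
  per_subj <- list()
  for (si in seq_along(tl)) {
    tr <- tl[[si]]
    tr <- tr[tr$session != "training" & !tr$excluded, , drop = FALSE]
    if (nrow(tr) == 0L) stop("no included experimental trials for a subject")
    opt <- .optimal_actions(env, tr)
    hit0 <- tr$a0 == opt$opt_a0
    hit1 <- tr$a1 == opt$opt_a1
    cell <- interaction(tr$condition, tr$uncertainty, drop = FALSE)
    for (cl in levels(cell)) {
      k <- cell == cl
      if (!any(k)) stop("empty condition cell in dataset")
      parts <- strsplit(cl, ".", fixed = TRUE)[[1]]
      per_subj[[length(per_subj) + 1L]] <- data.frame(
        subject = si, condition = parts[1], uncertainty = parts[2],
        shocks_avoided = mean(4 - tr$shocks[k]),
        success_rate = if (success_rule == "zero") mean(tr$shocks[k] == 0)
                       else mean(tr$shocks[k] < 4),
        optimal = mean(c(hit0[k], hit1[k])),
        optimal_stage1 = mean(hit0[k]),
        optimal_stage2 = mean(hit1[k])
      )
    }
  }
  per_subj <- do.call(rbind, per_subj)
  metrics <- c("shocks_avoided", "success_rate", "optimal",
               "optimal_stage1", "optimal_stage2")
  out <- list()
  for (cond in c("flexible", "specific")) {
    for (unc in c("low", "high")) {
      k <- per_subj$condition == cond & per_subj$uncertainty == unc
      base_r <- .cell_baseline(env, cond, unc, ideal = FALSE, success_rule)
      base_i <- .cell_baseline(env, cond, unc, ideal = TRUE, success_rule)
      for (m in metrics) {
        v <- per_subj[[m]][k]
        rb <- switch(m, shocks_avoided = base_r[["shocks_avoided"]],
                     success_rate = base_r[["success_rate"]], 0.5)
        ib <- switch(m, shocks_avoided = base_i[["shocks_avoided"]],
                     success_rate = base_i[["success_rate"]], 1)
        out[[length(out) + 1L]] <- data.frame(
          condition = cond, uncertainty = unc, metric = m,
          mean = mean(v), sem = sd(v) / sqrt(length(v)),
          random = rb, ideal = ib
        )
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "per_subject") <- per_subj
  class(out) <- c("avoid_summary", "data.frame")
  out
}

#' Likelihood-ratio comparison of controllers by arbitration regime
#'
#' Splits the included experimental trials of one subject into the regime
#' where the arbitrating model predicts model-free control (`p_MB < 0.5`)
#' and the regime where it predicts model-based control (`p_MB > 0.5`),
#' then sums, within each regime, the per-trial log-likelihood of the
#' independently fitted MB-only model minus the MF-only model. Negative
#' statistics mean the model-free learner accounts better for choice;
#' positive, the model-based learner. The two single-controller fits are
#' produced independently of the arbitrating model to avoid circularity.
#'
#' @param trials The subject's trial log.
#' @param trace The arbitrating model's latent trace for the same trials
#'   (supplies per-trial `p_mb`).
#' @param mf_fit,mb_fit `avoid_fit` objects for the MF-only and MB-only
#'   variants (or `agent_parameters` to evaluate directly).
#' @param env An `avoid_env` environment.
#' @param threshold Regime threshold on `p_mb` (default 0.5).
#' @return A list of class `avoid_rlr`: `statistic` (named: `mf_regime`,
#'   `mb_regime`), `n_trials` per regime, and `per_trial` (trial, `p_mb`,
#'   both log-likelihoods, their difference, regime).
#' @export
likelihood_ratio_regimes <- function(trials, trace, mf_fit, mb_fit, env,
                                     threshold = 0.5) {
  if (nrow(trials) != nrow(trace))
    stop("trace and trial log differ in length")
  as_params <- function(fit, variant) {
    if (inherits(fit, "agent_parameters")) return(fit)
    stopifnot(inherits(fit, "avoid_fit"))
    .build_params(fit$par, variant, fit$fixed)
  }
  ll_mf <- replay_agent(trials, as_params(mf_fit, "mf_only"), env,
                        "mf_only")$trace$ll
  ll_mb <- replay_agent(trials, as_params(mb_fit, "mb_only"), env,
                        "mb_only")$trace$ll
  keep <- trials$session != "training" & !trials$excluded
  pt <- data.frame(trial = trials$trial[keep], p_mb = trace$p_mb[keep],
                   ll_mf = ll_mf[keep], ll_mb = ll_mb[keep])
  pt$diff <- pt$ll_mb - pt$ll_mf
  pt$regime <- ifelse(pt$p_mb < threshold, "mf_regime", "mb_regime")
  stat <- c(mf_regime = sum(pt$diff[pt$regime == "mf_regime"]),
            mb_regime = sum(pt$diff[pt$regime == "mb_regime"]))
  structure(
    list(statistic = stat,
         n_trials = c(mf_regime = sum(pt$regime == "mf_regime"),
                      mb_regime = sum(pt$regime == "mb_regime")),
         per_trial = pt, threshold = threshold),
    class = "avoid_rlr"
  )
}

#' Group test of the regime likelihood-ratio statistic
#'
#' Tests, across subjects and (separately) across pooled trials, whether
#' the MB-minus-MF log-likelihood statistic differs from zero within each
#' arbitration regime. Both aggregations are reported because the analysis
#' admits either reading.
#'
#' @param rlrs List of `avoid_rlr` objects, one per subject.
#' @return Data frame with one row per regime and aggregation level:
#'   mean statistic, t statistic, degrees of freedom, p value.
#' @export
regime_group_test <- function(rlrs) {
  stopifnot(length(rlrs) >= 2, all(vapply(rlrs, inherits, TRUE, "avoid_rlr")))
  rows <- list()
  for (reg in c("mf_regime", "mb_regime")) {
    subj <- vapply(rlrs, function(r) r$statistic[[reg]], 0)
    tt <- t.test(subj)
    rows[[length(rows) + 1L]] <- data.frame(
      regime = reg, level = "subjects", mean = mean(subj),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
    pooled <- unlist(lapply(rlrs, function(r)
      r$per_trial$diff[r$per_trial$regime == reg]))
    tt <- t.test(pooled)
    rows[[length(rows) + 1L]] <- data.frame(
      regime = reg, level = "trials", mean = mean(pooled),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  }
  do.call(rbind, rows)
}

#' Compare fitted parameters between two groups of subjects
#'
#' Per-parameter t tests between two groups of per-subject fits: paired
#' when the groups are matched, two-sample otherwise (Welch unequal
#' variances by default). Degenerate comparisons with zero variance in the
#' differences (for example identical groups) are reported as
#' no-difference (`statistic = 0`, `p = 1`).
#'
#' @param fits_a,fits_b Lists of `avoid_fit` objects (>= 2 per group,
#'   same variant).
#' @param paired Matched groups?
#' @param var_equal Assume equal variances in the two-sample test?
#' @return Data frame: parameter, group means, t statistic, degrees of
#'   freedom, p value.
#' @export
compare_parameter_groups <- function(fits_a, fits_b, paired = FALSE,
                                     var_equal = FALSE) {
  get_mat <- function(fits) {
    stopifnot(all(vapply(fits, inherits, TRUE, "avoid_fit")))
    do.call(rbind, lapply(fits, function(f) f$par))
  }
  if (length(fits_a) < 2 || length(fits_b) < 2)
    stop("each group needs at least 2 fits")
  a <- get_mat(fits_a)
  b <- get_mat(fits_b)
  if (!identical(colnames(a), colnames(b)))
    stop("the two groups were fitted with different parameter sets")
  if (paired && nrow(a) != nrow(b))
    stop("paired comparison needs equally sized, matched groups")
  rows <- lapply(colnames(a), function(p) {
    res <- tryCatch(
      t.test(a[, p], b[, p], paired = paired, var.equal = var_equal),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$statistic))
      data.frame(parameter = p, mean_a = mean(a[, p]), mean_b = mean(b[, p]),
                 statistic = 0, df = NA_real_, p_value = 1)
    else
      data.frame(parameter = p, mean_a = mean(a[, p]), mean_b = mean(b[, p]),
                 statistic = unname(res$statistic),
                 df = unname(res$parameter), p_value = res$p.value)
  })
  do.call(rbind, rows)
}
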