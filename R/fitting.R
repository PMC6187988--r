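.free_params <- function(variant) {
  switch(variant,
         arbitrating = c("alpha", "eta", "omega", "amp_mf_to_mb",
                         "amp_mb_to_mf", "beta"),
         mf_only = c("alpha", "beta"),
         mb_only = c("alpha", "beta"),
         stop("unknown model variant"))
}

#' Default parameter bounds for fitting
#'
#' Search ranges used by [fit_parameters()]: learning rates in
#' \[0.01, 1\], the zero-SPE threshold in \[0.01, 0.99\], transition-rate
#' amplitudes in \[0.01, 1\] and the inverse temperature in \[0.01, 20\].
#' The simplex search runs in an unconstrained space reached by a scaled
#' logit transform of each bounded parameter.
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_bounds <- function() {
  list(alpha = c(0.01, 1), eta = c(0.01, 1), omega = c(0.01, 0.99),
       amp_mf_to_mb = c(0.01, 1), amp_mb_to_mf = c(0.01, 1),
       beta = c(0.01, 20))
}

.to_unconstrained <- function(x, b) qlogis((x - b[1]) / (b[2] - b[1]))
.from_unconstrained <- function(z, b) b[1] + (b[2] - b[1]) * plogis(z)

.build_params <- function(theta, variant, fixed) {
  base <- list(alpha = fixed$alpha, eta = fixed$eta, omega = fixed$omega,
               amp_mf_to_mb = fixed$amp_mf_to_mb,
               amp_mb_to_mf = fixed$amp_mb_to_mf, beta = fixed$beta)
  base[names(theta)] <- as.list(theta)
  agent_parameters(alpha = base$alpha, eta = base$eta, omega = base$omega,
                   amp_mf_to_mb = base$amp_mf_to_mb,
                   amp_mb_to_mf = base$amp_mb_to_mf, beta = base$beta,
                   B = fixed$B, bias_mf = fixed$bias_mf,
                   omega_max = fixed$omega_max, p_mb0 = fixed$p_mb0,
                   zspe0 = fixed$zspe0)
}

.as_trial_list <- function(trials) {
  if (is.data.frame(trials)) list(trials)
  else if (inherits(trials, "avoid_cohort")) lapply(trials, `[[`, "trials")
  else if (is.list(trials)) trials
  else stop("trials must be a data frame or a list of data frames")
}

#' Negative log-likelihood of observed choices under the model
#'
#' Replays the model teacher-forced along the observed choices and outcomes
#' and sums `-log P(a)` of every observed action over both stages of every
#' included trial (excluded penalising trials contribute nothing; training
#' choices are counted only if `include_training = TRUE`). Each choice
#' probability is floored at 1e-12 to guard against underflow.
#'
#' @param trials A trial log, or a list of trial logs (summed, e.g. for
#'   pooled fitting across subjects).
#' @param params An `agent_parameters` object.
#' @param env An `avoid_env` environment.
#' @param variant `"arbitrating"`, `"mf_only"` or `"mb_only"`.
#' @param include_training Count training-session choices?
#' @return The scalar NLL, with attribute `n_choices`.
#' @export
negative_log_likelihood <- function(trials, params, env,
                                    variant = c("arbitrating", "mf_only",
                                                "mb_only"),
                                    include_training = FALSE) {
  variant <- match.arg(variant)
  tl <- .as_trial_list(trials)
  nll <- 0
  nch <- 0L
  for (tr in tl) {
    rp <- replay_agent(tr, params, env, variant, include_training)
    nll <- nll + rp$nll
    nch <- nch + rp$n_choices
  }
  structure(nll, n_choices = nch)
}

#' Fit model parameters by multi-start Nelder-Mead maximum likelihood
#'
#' Minimises the negative log-likelihood of the observed choices with the
#' Nelder-Mead simplex algorithm, restarted from `n_restarts` uniform random
#' start points inside the bounds (function tolerance 1e-6, at most 2000
#' evaluations per restart; search in a scaled-logit transformed space so
#' the simplex is unconstrained). The arbitrating variant fits all six
#' parameters; the MF-only and MB-only variants fit `alpha` and `beta` with
#' the weight pinned (the remaining parameters do not enter their
#' likelihoods).
#'
#' @param trials A trial log or a list of trial logs (pooled fit).
#' @param env An `avoid_env` environment.
#' @param variant Model variant; see [negative_log_likelihood()].
#' @param n_restarts Number of random restarts (>= 1).
#' @param seed Seed for the restart draws (restart starts are a
#'   deterministic function of it).
#' @param bounds Named list of `c(lower, upper)` per free parameter;
#'   defaults to [default_bounds()].
#' @param fixed An `agent_parameters` object supplying the non-free
#'   parameters and constants.
#' @param include_training Count training-session choices in the NLL?
#' @return A list of class `avoid_fit`: `variant`, `par` (best parameters,
#'   natural scale), `nll`, `restarts` (per-restart start point, final NLL
#'   and convergence flag), `converged`, `n_trials`, `n_excluded`,
#'   `n_choices`.
#' @export
fit_parameters <- function(trials, env,
                           variant = c("arbitrating", "mf_only", "mb_only"),
                           n_restarts = 20, seed = NULL, bounds = NULL,
                           fixed = agent_parameters(),
                           include_training = FALSE) {
  variant <- match.arg(variant)
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  free <- .free_params(variant)
  b <- default_bounds()
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  b <- b[free]

  tl <- .as_trial_list(trials)
  enc <- lapply(tl, function(tr) list(plan = .encode_plan(tr),
                                      obs = .encode_observed(tr, env)))
  tmat <- .t_init_matrix(fixed)
  objective <- function(z) {
    theta <- setNames(mapply(.from_unconstrained, z, b), free)
    par <- .par_list(.build_params(theta, variant, fixed), variant)
    nll <- 0
    for (e in enc) {
      res <- .run_engine(env$enc$succ, env$enc$out_value, env$enc$out_colour,
                         unname(env$p_likely), par, e$plan, e$obs,
                         FALSE, include_training, tmat)
      nll <- nll + res$nll
    }
    if (!is.finite(nll)) 1e10 else nll
  }

  # restart k starts from a deterministic child seed of the master seed, so
  # enlarging n_restarts only appends start points (never changes earlier ones)
  if (!is.null(seed)) set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, n_restarts)
  starts <- t(vapply(seq_len(n_restarts), function(k) {
    set.seed(child[k])
    vapply(b, function(bb) runif(1, bb[1], bb[2]), 0)
  }, numeric(length(free))))
  colnames(starts) <- free

  restarts <- vector("list", n_restarts)
  best <- NULL
  for (k in seq_len(n_restarts)) {
    z0 <- mapply(.to_unconstrained, starts[k, ], b)
    opt <- optim(z0, objective, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-6))
    theta <- setNames(mapply(.from_unconstrained, opt$par, b), free)
    restarts[[k]] <- data.frame(restart = k,
                                as.list(setNames(starts[k, ],
                                                 paste0("start_", free))),
                                nll = opt$value,
                                converged = opt$convergence == 0L)
    if (is.null(best) || opt$value < best$value)
      best <- list(value = opt$value, theta = theta)
  }
  restarts <- do.call(rbind, restarts)

  n_trials <- sum(vapply(tl, nrow, 0L))
  n_excl <- sum(vapply(tl, function(x) sum(x$excluded), 0))
  nll0 <- negative_log_likelihood(tl, .build_params(best$theta, variant, fixed),
                                  env, variant, include_training)
  structure(
    list(variant = variant, par = best$theta, nll = best$value,
         restarts = restarts, converged = any(restarts$converged),
         n_trials = n_trials, n_excluded = n_excl,
         n_choices = attr(nll0, "n_choices"), fixed = fixed,
         include_training = include_training),
    class = "avoid_fit"
  )
}

#' @export
print.avoid_fit <- function(x, ...) {
  cat("Maximum-likelihood fit (", x$variant, " variant)\n", sep = "")
  cat("  NLL:", format(x$nll, digits = 6), "over", x$n_choices, "choices\n")
  cat("  parameters:\n")
  for (nm in names(x$par))
    cat(sprintf("    %-13s %.4g\n", nm, x$par[[nm]]))
  cat("  restarts:", nrow(x$restarts),
      sprintf("(%d converged)", sum(x$restarts$converged)), "\n")
  invisible(x)
}

#' Default sampler of subject-level generating parameters
#'
#' Draws parameters spread over plausible individual differences around the
#' generator defaults: learning rates uniform on \[0.2, 0.8\], zero-SPE
#' threshold uniform on \[0.2, 0.7\], amplitudes uniform on \[0.1, 0.7\]
#' and the inverse temperature log-uniform on \[1, 10\].
#'
#' @param n Number of subjects.
#' @return Data frame with one row per subject.
#' @export
default_param_sampler <- function(n) {
  data.frame(
    alpha = runif(n, 0.2, 0.8),
    eta = runif(n, 0.2, 0.8),
    omega = runif(n, 0.2, 0.7),
    amp_mf_to_mb = runif(n, 0.1, 0.7),
    amp_mb_to_mf = runif(n, 0.1, 0.7),
    beta = exp(runif(n, log(1), log(10)))
  )
}

#' Parameter-recovery study
#'
#' Simulates a cohort at known parameters, fits every subject independently
#' and summarises, per free parameter, the bias, root-mean-square error and
#' the Pearson and Spearman correlations between true and recovered values
#' -- the standard validation that the fitting machinery can retrieve the
#' parameters that generated the data.
#'
#' @param n_subjects Number of simulated subjects (>= 2).
#' @param param_sampler Sampler of generating parameters; see
#'   [simulate_cohort()].
#' @param config Task configuration.
#' @param seed Master seed for simulation and restart draws.
#' @param n_restarts Restarts per subject fit.
#' @param variant Model variant fitted (and simulated).
#' @return A list of class `avoid_recovery`: `table` (per-parameter
#'   summary), `true`, `recovered`, `fits`.
#' @export
parameter_recovery <- function(n_subjects = 15,
                               param_sampler = default_param_sampler,
                               config = default_task_config(), seed = 1,
                               n_restarts = 20, variant = "arbitrating") {
  if (n_subjects < 2) stop("parameter recovery needs at least 2 subjects")
  cohort <- simulate_cohort(n_subjects, param_sampler, config, seed,
                            kind = if (variant == "arbitrating") "arbitrating"
                                   else variant)
  env <- build_environment(config)
  free <- .free_params(variant)
  true <- do.call(rbind, lapply(cohort, function(s)
    as.data.frame(s$params[free])))
  fits <- vector("list", n_subjects)
  rec <- matrix(NA_real_, n_subjects, length(free),
                dimnames = list(NULL, free))
  for (i in seq_len(n_subjects)) {
    fits[[i]] <- fit_parameters(cohort[[i]]$trials, env, variant,
                                n_restarts = n_restarts,
                                seed = cohort[[i]]$seed)
    rec[i, ] <- fits[[i]]$par[free]
  }
  rec <- as.data.frame(rec)
  tab <- data.frame(
    parameter = free,
    bias = vapply(free, function(p) mean(rec[[p]] - true[[p]]), 0),
    rmse = vapply(free, function(p) sqrt(mean((rec[[p]] - true[[p]])^2)), 0),
    pearson = vapply(free, function(p) cor(true[[p]], rec[[p]]), 0),
    spearman = vapply(free, function(p)
      cor(true[[p]], rec[[p]], method = "spearman"), 0),
    row.names = NULL
  )
  structure(list(table = tab, true = true, recovered = rec, fits = fits),
            class = "avoid_recovery")
}

#' @export
print.avoid_recovery <- function(x, ...) {
  cat("Parameter recovery over", nrow(x$true), "simulated subjects\n")
  print(x$table, digits = 3)
  invisible(x)
}
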