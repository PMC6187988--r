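#' Initialise the reliability estimators
#'
#' The model-free reliability is driven by an estimator `Omega` that tracks
#' the absolute outcome prediction error: `Omega <- Omega + eta * (|OPE| -
#' Omega)`. If the estimator predicts zero OPE the model-free reliability is
#' maximal: `chi_MF = max(0, 1 - Omega / omega_max)`. The model-based
#' reliability counts a transition as perfectly predicted whenever its state
#' prediction error falls below the threshold `omega`; the reliability is
#' the exponentially weighted rate of such zero-SPE transitions (same
#' learning rate `eta`), reaching 1 when every recent SPE is below
#' threshold.
#'
#' @param eta Learning rate of both reliability estimators, in (0, 1].
#' @param omega Zero-SPE threshold in (0, 1).
#' @param omega_max Normaliser of the model-free reliability; the largest
#'   absolute OPE the outcome range can produce (default 4: outcomes occur
#'   only at the terminal transition, so values stay in \[-4, 0\] and no
#'   prediction error can exceed 4 in magnitude).
#' @param zspe0 Starting value of the zero-SPE rate.
#' @return A list of class `reliability_state` with fields `Omega`, `zspe`,
#'   `chi_mf`, `chi_mb` and the constants.
#' @export
reliability_init <- function(eta = 0.5, omega = 0.45, omega_max = 4,
                             zspe0 = 0.5) {
  if (!is.numeric(eta) || eta <= 0 || eta > 1)
    stop("eta must lie in (0, 1]")
  if (!is.numeric(omega) || omega <= 0 || omega >= 1)
    stop("omega must lie in (0, 1)")
  structure(
    list(eta = eta, omega = omega, omega_max = omega_max,
         Omega = 0, zspe = zspe0, chi_mf = 1, chi_mb = zspe0),
    class = "reliability_state"
  )
}

#' Update the model-free reliability from an outcome prediction error
#'
#' @param rel A `reliability_state`.
#' @param ope Signed outcome prediction error.
#' @return The updated `reliability_state`.
#' @examples
#' rel <- reliability_init(eta = 0.5)
#' update_mf_reliability(rel, -4)$Omega # 2
#' @export
update_mf_reliability <- function(rel, ope) {
  stopifnot(inherits(rel, "reliability_state"))
  rel$Omega <- rel$Omega + rel$eta * (abs(ope) - rel$Omega)
  rel$chi_mf <- max(0, 1 - rel$Omega / rel$omega_max)
  rel
}

#' Update the model-based reliability from a state prediction error
#'
#' @param rel A `reliability_state`.
#' @param spe State prediction error in \[0, 1\].
#' @return The updated `reliability_state`.
#' @export
update_mb_reliability <- function(rel, spe) {
  stopifnot(inherits(rel, "reliability_state"))
  if (!is.numeric(spe) || spe < 0 || spe > 1)
    stop("SPE must lie in [0, 1]")
  ind <- as.numeric(spe < rel$omega)
  rel$zspe <- rel$zspe + rel$eta * (ind - rel$zspe)
  rel$chi_mb <- rel$zspe
  rel
}

#' Initialise the two-state arbitration dynamics
#'
#' Control is allocated by a dynamical two-state transition model whose
#' states are the probabilities of choosing each controller, `p_MF` and
#' `p_MB = 1 - p_MF`. The transition rates are logistic functions of the
#' reliability difference, scaled by free amplitudes, with a fixed
#' multiplicative bias favouring model-free control when the reliabilities
#' are equal (habits dominate with training).
#'
#' @param amp_mf_to_mb,amp_mb_to_mf Positive amplitudes of the MF-to-MB and
#'   MB-to-MF transition rates.
#' @param B Fixed logistic steepness (default 10).
#' @param bias_mf Fixed multiplier (>= 1) on the MB-to-MF rate.
#' @param p_mb0 Starting weight on the model-based controller.
#' @return A list of class `arbitration_state`.
#' @export
arbitration_init <- function(amp_mf_to_mb = 0.5, amp_mb_to_mf = 0.3, B = 10,
                             bias_mf = 1.5, p_mb0 = 0.5) {
  if (amp_mf_to_mb <= 0 || amp_mb_to_mf <= 0)
    stop("transition-rate amplitudes must be positive")
  if (bias_mf < 1) stop("bias_mf must be >= 1")
  if (p_mb0 < 0 || p_mb0 > 1) stop("p_mb0 must lie in [0, 1]")
  structure(
    list(amp_mf_to_mb = amp_mf_to_mb, amp_mb_to_mf = amp_mb_to_mf, B = B,
         bias_mf = bias_mf, p_mb = p_mb0),
    class = "arbitration_state"
  )
}

#' One step of the controller-weight dynamics
#'
#' `p_MB <- p_MB + tau_MF->MB * (1 - p_MB) - tau_MB->MF * p_MB`, with
#' `tau_MF->MB = A_MF->MB * sigma(B * (chi_MB - chi_MF))` and
#' `tau_MB->MF = bias_MF * A_MB->MF * sigma(B * (chi_MF - chi_MB))`,
#' `sigma` the logistic function. The result is clipped to \[0, 1\].
#'
#' @param arb An `arbitration_state`.
#' @param chi_mf,chi_mb Controller reliabilities in \[0, 1\].
#' @return The updated `arbitration_state` (rates stored in `tau_mf_to_mb`,
#'   `tau_mb_to_mf`).
#' @export
update_controller_weight <- function(arb, chi_mf, chi_mb) {
  stopifnot(inherits(arb, "arbitration_state"))
  if (chi_mf < 0 || chi_mf > 1 || chi_mb < 0 || chi_mb > 1)
    stop("reliabilities must lie in [0, 1]")
  t12 <- arb$amp_mf_to_mb * plogis(arb$B * (chi_mb - chi_mf))
  t21 <- arb$bias_mf * arb$amp_mb_to_mf * plogis(arb$B * (chi_mf - chi_mb))
  p <- arb$p_mb + t12 * (1 - arb$p_mb) - t21 * arb$p_mb
  arb$p_mb <- min(1, max(0, p))
  arb$tau_mf_to_mb <- t12
  arb$tau_mb_to_mf <- t21
  arb
}

#' Convex combination of the two controllers' values
#'
#' `Q = p_MB * Q_MB + (1 - p_MB) * Q_MF`, elementwise.
#'
#' @param q_mf,q_mb Value tables (or rows) sharing dimensions and names.
#' @param p_mb Weight on the model-based values, in \[0, 1\].
#' @return The integrated value table.
#' @export
integrate_values <- function(q_mf, q_mb, p_mb) {
  if (p_mb < 0 || p_mb > 1) stop("p_mb must lie in [0, 1]")
  if (!identical(dim(q_mf), dim(q_mb)) ||
      !identical(dimnames(q_mf), dimnames(q_mb)) ||
      length(q_mf) != length(q_mb))
    stop("value tables must share their index sets")
  p_mb * q_mb + (1 - p_mb) * q_mf
}

#' Softmax choice probabilities
#'
#' `P(a) = exp(beta * Q_a) / sum_a' exp(beta * Q_a')`, computed stably
#' (shift-invariant) for an inverse temperature `beta >= 0`.
#'
#' @param q Numeric vector of action values at one state.
#' @param beta Inverse temperature, >= 0.
#' @return Probability vector over the actions, summing to 1.
#' @examples
#' softmax_choice_prob(c(0, -1), beta = 1) # about 0.731, 0.269
#' @export
softmax_choice_prob <- function(q, beta) {
  if (!all(is.finite(q))) stop("action values must be finite")
  if (!is.numeric(beta) || beta < 0) stop("beta must be >= 0")
  z <- beta * (q - max(q))
  e <- exp(z)
  p <- e / sum(e)
  names(p) <- names(q)
  p
}
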