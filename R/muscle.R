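# Muscle force generation: maximal-force-scaled activation plus a parallel
# passive elastic (PE) element; force-length and force-velocity scaling are
# deliberately absent from this model.

#' Passive elastic (PE) element force
#'
#' \deqn{f^{PE} = k_1^{PE} [\exp\{k_2^{PE} (L - \bar L)\} - 1]}
#' As printed this admits a small compressive force (bounded below by
#' \eqn{-k_1^{PE}}) when the muscle is shorter than its rest length; set
#' `clamp_nonnegative` in the model's `pe_params` (or pass a params list with
#' it) for the conventional tension-only behaviour.
#'
#' @param params an `msk_model` or a list with `k1_pe`, `k2_pe` and optional
#'   `clamp_nonnegative`.
#' @param L muscle length (m), > 0.
#' @param L_rest rest length (m).
#' @return force (N).
#' @export
pe_force <- function(params, L, L_rest) {
  if (inherits(params, "msk_model")) params <- params$pe_params
  stopifnot(all(L > 0))
  f <- params$k1_pe * (exp(params$k2_pe * (L - L_rest)) - 1)
  if (isTRUE(params$clamp_nonnegative)) f <- pmax(f, 0)
  f
}

#' Total muscle force
#'
#' \deqn{f_m = F^{MAX}_m a_m + f^{PE}_m}: the active component is the maximal
#' isometric force scaled by the activation signal, with no force-length or
#' force-velocity dependence.
#'
#' @param spec a muscle spec (element of `model$muscles`) or a list with
#'   `f_max`.
#' @param a activation in `[0, 1]`.
#' @param f_pe PE force (N), e.g. from [pe_force()].
#' @return list with `total`, `active`, `pe` (N).
#' @export
muscle_force <- function(spec, a, f_pe = 0) {
  if (any(!is.finite(a)) || any(a < 0 | a > 1))
    stop("activation must be within [0, 1]")
  active <- spec$f_max * a
  list(total = active + f_pe, active = active, pe = f_pe)
}

#' Joint moments produced by a set of muscle forces
#'
#' Moment at joint j is \eqn{\sum_m f_m \, r_{m,j}(q)} with posture-dependent
#' moment arms \eqn{r_{m,j} = -\partial L_m/\partial\theta_j}; biarticular
#' muscles contribute to both spanned joints.
#'
#' @param model an `msk_model`.
#' @param q named joint angles (rad) for one leg.
#' @param forces named or ordered vector of 10 muscle forces (N).
#' @return named vector of moments (N m) at hip, knee, ankle, MP.
#' @export
muscle_joint_moments <- function(model, q, forces) {
  stopifnot(length(forces) == length(model$muscles))
  tau <- stats::setNames(numeric(4), JOINT_NAMES)
  for (m in seq_along(model$muscles)) {
    mus <- model$muscles[[m]]
    for (j in mus$spanned_joints)
      tau[j] <- tau[j] + forces[[m]] * moment_arm(model, q, mus$name, j)
  }
  tau
}
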