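# Energetics: muscle mechanical work, gross metabolic cost of transport,
# COM mechanical energies and pendular %recovery.

#' Positive and negative mechanical work of the muscles
#'
#' Contractile-element power is \eqn{p_m = (F^{MAX}_m a_m)(-dL_m/dt)}
#' (positive when an active muscle shortens); positive and negative work are
#' the time integrals of its positive and negative parts.  PE-element power
#' is excluded by default: the PE spring is conservative, and charging its
#' elastic return against the metabolic budget would contradict the
#' elastic-storage mechanism the model is meant to capture.
#'
#' Trials produced by [simulate_gait()] carry work accumulators integrated at
#' the full integration rate; those are used when present unless
#' `from_traces = TRUE` forces re-integration from the recorded (subsampled)
#' traces.
#'
#' @param trial a `gait_trial`.
#' @param from_traces integrate from recorded activation/length traces
#'   instead of the in-loop accumulators.
#' @param include_pe include PE power in the trace-based integration.
#' @return data.frame with per-muscle `W_pos` (J, >= 0) and `W_neg` (J, <= 0).
#' @export
muscle_work <- function(trial, from_traces = FALSE, include_pe = FALSE) {
  if (!from_traces && !is.null(trial$work_pos)) {
    return(data.frame(muscle = names(trial$work_pos),
                      W_pos = unname(trial$work_pos),
                      W_neg = unname(trial$work_neg),
                      stringsAsFactors = FALSE))
  }
  t <- trial$time
  n <- length(t)
  ldot <- apply(trial$muscle_len, 2, function(L) {
    c(diff(L) / diff(t), 0)
  })
  f <- sweep(trial$act, 2, trial$f_max[colnames(trial$act)], `*`)
  if (include_pe) f <- f + trial$f_pe
  p <- -f * ldot
  w <- function(x) sum((x[-n] * diff(t)))
  data.frame(muscle = colnames(trial$act),
             W_pos = apply(pmax(p, 0), 2, w),
             W_neg = apply(pmin(p, 0), 2, w),
             stringsAsFactors = FALSE)
}

#' Assemble an energy budget for a trial
#'
#' @param trial a `gait_trial`.
#' @param basal_rate mass-specific basal metabolic rate (W/kg); a calibration
#'   constant that offsets the cost of transport without affecting
#'   morphing trends.
#' @param eta_pos,eta_neg muscular efficiencies of positive and negative
#'   work (classic values 0.25 and 1.2).
#' @param ... passed to [muscle_work()].
#' @return list of class `energy_budget`.
#' @export
energy_budget <- function(trial, basal_rate = 2.0, eta_pos = 0.25,
                          eta_neg = 1.2, ...) {
  w <- muscle_work(trial, ...)
  structure(list(
    work = w,
    basal_power = basal_rate * trial$total_mass,
    duration = trial$t_end,
    distance = trial$distance,
    mass = trial$total_mass,
    eta_pos = eta_pos, eta_neg = eta_neg
  ), class = "energy_budget")
}

#' Gross metabolic cost of transport
#'
#' \deqn{COT = \frac{\sum_m (W^+_m/\eta^+ + |W^-_m|/\eta^-) + P_{basal} T}
#'   {M D}}
#' mass-specific metabolic energy per distance travelled, J/(kg m).
#'
#' @param budget an [energy_budget()], or a `gait_trial` (a budget with
#'   default calibration is built on the fly).
#' @param ... passed to [energy_budget()] when `budget` is a trial.
#' @return cost of transport, J/(kg m).
#' @export
cost_of_transport <- function(budget, ...) {
  if (inherits(budget, "gait_trial")) budget <- energy_budget(budget, ...)
  if (!(budget$distance > 0)) stop("distance must be > 0")
  e_musc <- sum(budget$work$W_pos / budget$eta_pos +
                  abs(budget$work$W_neg) / budget$eta_neg)
  (e_musc + budget$basal_power * budget$duration) /
    (budget$mass * budget$distance)
}

#' COM mechanical energy traces
#'
#' Potential energy \eqn{E_p = M g h_{COM}}, kinetic energy \eqn{E_k =
#' \frac{1}{2} M |v_{COM}|^2} and their sum (the external energy) from the
#' segment-mass-weighted whole-body centre of mass.
#'
#' @param trial a `gait_trial` (or any list with `time`, `com`, `vcom`,
#'   `total_mass` and a gravity of 9.81 implied by the model).
#' @param gravity gravitational acceleration (m/s^2).
#' @return data.frame `time`, `Ep`, `Ek`, `Eext`.
#' @export
com_energy <- function(trial, gravity = 9.81) {
  M <- trial$total_mass
  Ep <- M * gravity * trial$com[, "com_y"]
  Ek <- 0.5 * M * (trial$vcom[, "vcom_x"]^2 + trial$vcom[, "vcom_y"]^2)
  data.frame(time = trial$time, Ep = Ep, Ek = Ek, Eext = Ep + Ek)
}

#' Pendular energy recovery (%recovery)
#'
#' The fraction of COM mechanical energy recovered by out-of-phase exchange
#' of potential and kinetic energy (the inverted-pendulum mechanism),
#' \deqn{R = 100 \frac{\sum \Delta^+ E_p + \sum \Delta^+ E_k -
#'   \sum \Delta^+ E_{ext}}{\sum \Delta^+ E_p + \sum \Delta^+ E_k}}
#' where \eqn{\sum \Delta^+} sums the positive increments of a trace over the
#' analysed window (standard external-work formulation).  Apply over an
#' integer number of strides.
#'
#' @param trace data.frame from [com_energy()] (optionally windowed).
#' @return percentage in `[0, 100]`; `NA` if the denominator is zero.
#' @export
percent_recovery <- function(trace) {
  dpos <- function(x) sum(pmax(diff(x), 0))
  wp <- dpos(trace$Ep); wk <- dpos(trace$Ek); wext <- dpos(trace$Eext)
  if (wp + wk == 0) return(NA_real_)
  100 * (wp + wk - wext) / (wp + wk)
}
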