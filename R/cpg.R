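# Two-layer CPG controller: rhythm-generation phase oscillators with
# touchdown phase resetting, Gaussian pattern formation, and trunk posture
# feedback through the hip uniarticular muscles.

#' CPG rhythm-generator parameters
#'
#' Coupled phase oscillators, one per leg, with intrinsic frequency
#' \eqn{\omega = 2\pi/T} and mutual coupling that stabilizes anti-phase
#' (alternating) stepping.
#'
#' @param T gait cycle period (s), default 0.747.
#' @param K coupling gain, default 1.
#' @return list of class `cpg_params`.
#' @export
cpg_params <- function(T = 0.747, K = 1) {
  stopifnot(T > 0)
  structure(list(T = T, K = K, omega = 2 * pi / T), class = "cpg_params")
}

#' Advance the two leg oscillators one Euler step
#'
#' \deqn{\dot\phi_R = \omega - K \sin(\phi_R - \phi_L - \pi), \quad
#'       \dot\phi_L = \omega - K \sin(\phi_L - \phi_R - \pi)}
#' Phases are wrapped into `[0, 2pi)`.
#'
#' @param params [cpg_params()].
#' @param phi_R,phi_L current phases (rad).
#' @param dt time step (s).
#' @return named vector `c(phi_R, phi_L)`.
#' @export
oscillator_step <- function(params, phi_R, phi_L, dt) {
  stopifnot(dt >= 0)
  dR <- params$omega - params$K * sin(phi_R - phi_L - pi)
  dL <- params$omega - params$K * sin(phi_L - phi_R - pi)
  c(phi_R = (phi_R + dt * dR) %% (2 * pi),
    phi_L = (phi_L + dt * dL) %% (2 * pi))
}

#' Reset oscillator phase at touchdown
#'
#' Sets the touching leg's phase to 0 (foot-ground contact defines \eqn{\phi
#' = 0}); the other leg is untouched.  A simultaneous bilateral touchdown
#' resets both.
#'
#' @param phases named vector `c(phi_R, phi_L)`.
#' @param leg `"R"`, `"L"`, or a character vector of both.
#' @return updated phases.
#' @export
reset_phase <- function(phases, leg) {
  if ("R" %in% leg) phases[1] <- 0
  if ("L" %in% leg) phases[2] <- 0
  phases
}

#' Muscle activation pattern from the pattern-formation layer
#'
#' A mixture of two Gaussian-shaped bells of the leg phase,
#' \deqn{\bar a(\phi) = \frac{\gamma}{\sqrt{2\pi}\sigma_1}
#'   e^{-(\phi-\mu_1)^2/(2\sigma_1)} + \frac{1-\gamma}{\sqrt{2\pi}\sigma_2}
#'   e^{-(\phi-\mu_2)^2/(2\sigma_2)},}
#' normalized by its maximum (taken numerically on a fixed 2048-point phase
#' grid) and scaled by the gain \eqn{\delta}.  Note the exponent denominator
#' is \eqn{2\sigma}, not \eqn{2\sigma^2}: the width parameters carry units of
#' rad^2.  By default the bells are periodically extended with images at
#' \eqn{\phi \pm 2\pi} so the pattern is continuous across the phase wrap; set
#' `periodic = FALSE` for the literal aperiodic form.
#'
#' @param pattern list or vector with `gamma`, `delta`, `mu1`, `mu2`,
#'   `sigma1`, `sigma2`.
#' @param phi phase(s) in `[0, 2pi)` (values outside are accepted and used
#'   as-is).
#' @param periodic use the periodic extension (default TRUE).
#' @return activation value(s); the maximum over the grid equals `delta`.
#' @export
pattern_activation <- function(pattern, phi, periodic = TRUE) {
  p <- as.list(pattern)
  if (p$sigma1 <= 0 || p$sigma2 <= 0) stop("sigma parameters must be > 0")
  raw <- function(x) {
    p$gamma / (sqrt(2 * pi) * p$sigma1) * exp(-(x - p$mu1)^2 / (2 * p$sigma1)) +
      (1 - p$gamma) / (sqrt(2 * pi) * p$sigma2) *
        exp(-(x - p$mu2)^2 / (2 * p$sigma2))
  }
  f <- if (periodic) function(x) raw(x) + raw(x - 2 * pi) + raw(x + 2 * pi)
       else raw
  grid <- 2 * pi * (0:2047) / 2048
  mx <- max(f(grid))
  if (mx <= 0) return(rep(0, length(phi)))
  p$delta * f(phi) / mx
}

#' Convert a 60-parameter genome to per-muscle patterns and back
#'
#' The flat genome is ordered (muscle 1..10) x (gamma, delta, mu1, mu2,
#' sigma1, sigma2), matching the text serialization of [write_genome()].
#'
#' @param genome numeric vector of length 60.
#' @return `genome_to_patterns`: a 10 x 6 matrix with muscle rows; columns
#'   `gamma`, `delta`, `mu1`, `mu2`, `sigma1`, `sigma2`.
#' @export
genome_to_patterns <- function(genome) {
  stopifnot(length(genome) == 60)
  m <- matrix(as.numeric(genome), nrow = 10, ncol = 6, byrow = TRUE)
  dimnames(m) <- list(MUSCLE_NAMES,
                      c("gamma", "delta", "mu1", "mu2", "sigma1", "sigma2"))
  m
}

#' @rdname genome_to_patterns
#' @param patterns a 10 x 6 pattern matrix.
#' @export
patterns_to_genome <- function(patterns) {
  stopifnot(nrow(patterns) == 10, ncol(patterns) == 6)
  as.numeric(t(patterns))
}

#' Read / write a genome as plain text
#'
#' One line per muscle: name, gamma, delta, mu1, mu2, sigma1, sigma2,
#' whitespace separated, with a header line.
#'
#' @param genome numeric vector of length 60.
#' @param path file path.
#' @export
write_genome <- function(genome, path) {
  m <- genome_to_patterns(genome)
  df <- data.frame(muscle = rownames(m), m, check.names = FALSE)
  utils::write.table(format(df, digits = 17), path, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 10)
  patterns_to_genome(as.matrix(df[, c("gamma", "delta", "mu1", "mu2",
                                      "sigma1", "sigma2")]))
}

#' Build a CPG controller for the simulator
#'
#' Bundles the genome (pattern-formation parameters for the ten muscles,
#' shared by both legs), the rhythm-generator parameters and the trunk
#' posture feedback into the controller queried by [simulate_gait()] at
#' every integration step.  The oscillator phase of a leg is reset to 0 at
#' each of its touchdowns.
#'
#' @param genome numeric vector of length 60 (see [genome_to_patterns()]).
#' @param cpg [cpg_params()].
#' @param kappa posture feedback gain (activation/rad), default 5.
#' @param theta_ref reference trunk pitch (rad, positive forward lean).
#' @param periodic periodic extension of the Gaussian patterns.
#' @param ramp_time soft-start duration (s): the pattern drive is scaled by
#'   `min(1, t/ramp_time)` so the standing model eases into the gait; 0
#'   disables the ramp.  Posture feedback is not ramped.
#' @param reset_window touchdown phase resets are accepted only when the
#'   leg's oscillator phase is at least this value (rad): genuine post-swing
#'   contacts reset the rhythm, while contact chatter earlier in the cycle
#'   must not resynchronize the two legs.
#' @return controller object for [simulate_gait()].
#' @export
cpg_controller <- function(genome, cpg = cpg_params(), kappa = 5,
                           theta_ref = 0.3, periodic = TRUE,
                           ramp_time = 0.4, reset_window = pi) {
  pat <- genome_to_patterns(genome)
  if (any(pat[, c("sigma1", "sigma2")] <= 0))
    stop("sigma parameters must be > 0")
  list(type = "cpg", genome = unname(pat), cpg = cpg,
       posture = list(kappa = kappa, theta_ref = theta_ref),
       periodic = periodic, ramp_time = ramp_time,
       reset_window = reset_window)
}

#' Controller output: 20 muscle activations
#'
#' R-side mirror of the in-loop controller: pattern activations evaluated at
#' each leg's phase, plus the trunk posture correction
#' \deqn{a^{pc}_{IL} = \kappa \max(\bar\theta - \theta_{HAT}, 0), \quad
#'       a^{pc}_{GMED} = \kappa \max(\theta_{HAT} - \bar\theta, 0)}
#' added to the hip uniarticular muscles of legs in ground contact (vertical
#' GRF above threshold; both legs during double support).  Output clamped to
#' `[0, 1]`.
#'
#' @param controller a [cpg_controller()].
#' @param phases `c(phi_R, phi_L)`.
#' @param pitch trunk pitch (rad).
#' @param grf_vert `c(right, left)` vertical GRF (N).
#' @param grf_threshold support threshold (N).
#' @return named activation vector of length 20 (right leg 1-10, then left).
#' @export
controller_output <- function(controller, phases, pitch, grf_vert,
                              grf_threshold = 1) {
  if (!is.finite(pitch)) stop("trunk pitch is not finite")
  pat <- controller$genome
  a <- numeric(20)
  for (leg in 1:2) {
    for (m in 1:10) {
      a[10 * (leg - 1) + m] <- pattern_activation(
        stats::setNames(as.list(pat[m, ]),
                        c("gamma", "delta", "mu1", "mu2", "sigma1", "sigma2")),
        phases[leg], controller$periodic)
    }
  }
  kap <- controller$posture$kappa
  tref <- controller$posture$theta_ref
  a_il <- kap * max(tref - pitch, 0)
  a_gl <- kap * max(pitch - tref, 0)
  for (leg in 1:2) {
    if (grf_vert[leg] > grf_threshold) {
      a[10 * (leg - 1) + 1] <- a[10 * (leg - 1) + 1] + a_il
      a[10 * (leg - 1) + 2] <- a[10 * (leg - 1) + 2] + a_gl
    }
  }
  stats::setNames(pmin(1, pmax(0, a)),
                  c(paste0(MUSCLE_NAMES, "_R"), paste0(MUSCLE_NAMES, "_L")))
}
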