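# Closed-loop forward dynamics: simulation driver, single stepping, fall
# detection, passive joint moments, and R-side kinematics used as an
# independent oracle for the compiled core.

#' Default initial state: quiet digitigrade standing
#'
#' Builds a standing posture on the forefeet (heel off the ground, MP joints
#' dorsiflexed so the phalanges lie flat) with a small forward push.  The hip
#' height is chosen so the lowest contact point starts with ~2 mm of ground
#' penetration, i.e. near static vertical equilibrium of the penalty-based
#' contact.
#'
#' @param model an `msk_model`.
#' @param pitch,hip,knee,ankle trunk pitch and stance-leg (right) joint
#'   angles (rad); the MP angle is set so the phalangeal segment is
#'   horizontal.
#' @param left_offsets additive joint offsets (rad) putting the left leg in
#'   a late-stance posture (hip more extended, foot grounded behind the
#'   body), consistent with its oscillator phase starting half a cycle ahead
#'   of the right leg; alternation is thereby established from the first
#'   step instead of bilateral hopping.
#' @param forward_velocity initial horizontal velocity (m/s).
#' @param settle penetration depth (m) of the lowest contact point; `NULL`
#'   (default) solves for the depth at which the contact springs carry the
#'   body weight, so the stance starts near vertical equilibrium.
#' @return list with `q` (11), `qd` (11) and `phases` (right, left).
#' @export
default_init_state <- function(model, pitch = 0.3, hip = 1.0, knee = -0.8,
                               ankle = 1.1,
                               left_offsets = c(hip = -0.45, knee = -0.25,
                                                ankle = 0.25),
                               forward_velocity = 0.5, settle = NULL) {
  mp_flat <- function(p, h, k, a) {
    psi_foot <- -pi / 2 - p + h + k + a
    max(min(-psi_foot, model$joint_ranges$mp[2]), model$joint_ranges$mp[1])
  }
  qR <- c(hip, knee, ankle, mp_flat(pitch, hip, knee, ankle))
  hL <- hip + left_offsets[["hip"]]
  kL <- knee + left_offsets[["knee"]]
  aL <- ankle + left_offsets[["ankle"]]
  qL <- c(hL, kL, aL, mp_flat(pitch, hL, kL, aL))
  q <- c(0, 0, pitch, qR, qL)
  # contact point heights with hip at y = 0
  heights <- as.vector(vapply(seq_len(nrow(model$contact$layout)), function(i) {
    lay <- model$contact$layout[i, ]
    sapply(list(qR, qL), function(ql) {
      point_world(model, lay$segment, c(lay$x, lay$y),
                  c(pitch, ql), base = c(0, 0))[2]
    })
  }, numeric(2)))
  low <- min(heights)
  if (is.null(settle)) {
    # depth at which the vertical contact springs carry the body weight
    weight <- total_mass(model) * model$gravity
    k <- model$contact$params$k_vert
    f <- function(d) sum(k * pmax(0, -(heights - low - d))) - weight
    settle <- stats::uniroot(f, c(1e-6, 0.05))$root
  }
  q[2] <- -low - settle
  list(q = q, qd = c(forward_velocity, rep(0, 10)), phases = c(0, pi))
}

.sim_options <- function(contact_on = TRUE, muscles_on = TRUE,
                         passive_on = TRUE, gravity_on = TRUE,
                         stop_on_fall = TRUE) {
  list(contact_on = contact_on, muscles_on = muscles_on,
       passive_on = passive_on, gravity_on = gravity_on,
       stop_on_fall = stop_on_fall)
}

#' Run a closed-loop gait simulation
#'
#' Integrates the 11-DOF equation of motion at a fixed time step with the
#' controller queried every step, and records states, activations, muscle
#' forces (total / active / PE), per-leg ground reaction forces, centre of
#' pressure, oscillator phases, whole-body COM kinematics and foot contact
#' events.  The trial terminates early when the model falls (HAT too low or
#' trunk pitch beyond the configured limit).
#'
#' @param model an `msk_model`.
#' @param controller a controller from [cpg_controller()] or
#'   [fixed_controller()].
#' @param duration simulated time (s).
#' @param dt integration step (s), default 1e-4.
#' @param record_dt sampling interval of the recorded time series (s).
#' @param init initial state from [default_init_state()] (default) or a
#'   compatible list.
#' @param on_nonfinite `"error"` to stop on non-finite states, `"fall"` to
#'   record them as a fall (used inside optimization).
#' @param options advanced physics toggles (internal, for testing).
#' @return a `gait_trial` object.
#' @export
simulate_gait <- function(model, controller, duration = 15, dt = 1e-4,
                          record_dt = 1e-3, init = NULL,
                          on_nonfinite = c("error", "fall"),
                          options = .sim_options()) {
  on_nonfinite <- match.arg(on_nonfinite)
  stopifnot(duration > 0, dt > 0)
  if (is.null(init)) init <- default_init_state(model)
  record_every <- max(1L, as.integer(round(record_dt / dt)))
  raw <- .sim_run(model, controller, init$q, init$qd, init$phases,
                  duration, dt, record_every, options)
  if (raw$nonfinite && on_nonfinite == "error")
    stop("integration produced a non-finite state at t = ", raw$t_end, " s")
  .as_gait_trial(raw, model, dt, record_every)
}

.as_gait_trial <- function(raw, model, dt, record_every) {
  n <- raw$n_rec
  ix <- seq_len(n)
  mn <- vapply(model$muscles, `[[`, "", "name")
  colnames20 <- c(paste0(mn, "_R"), paste0(mn, "_L"))
  ev <- data.frame(time = raw$events$time,
                   leg = c("R", "L")[raw$events$leg + 1L],
                   type = c("touchdown", "toeoff")[raw$events$type],
                   stringsAsFactors = FALSE)
  name_mat <- function(m, cols) { m <- m[ix, , drop = FALSE]; colnames(m) <- cols; m }
  structure(list(
    time = raw$time[ix],
    q = name_mat(raw$q, c("x", "y", "pitch",
                          paste0(JOINT_NAMES, "_R"), paste0(JOINT_NAMES, "_L"))),
    qd = name_mat(raw$qd, c("vx", "vy", "pitch_rate",
                            paste0(JOINT_NAMES, "_R_rate"),
                            paste0(JOINT_NAMES, "_L_rate"))),
    phases = name_mat(raw$phases, c("phi_R", "phi_L")),
    act = name_mat(raw$act, colnames20),
    f_total = name_mat(raw$f_total, colnames20),
    f_active = name_mat(raw$f_active, colnames20),
    f_pe = name_mat(raw$f_pe, colnames20),
    muscle_len = name_mat(raw$muscle_len, colnames20),
    grf = name_mat(raw$grf, c("vert_R", "horz_R", "vert_L", "horz_L")),
    cop = name_mat(raw$cop, c("cop_R", "cop_L")),
    stance = name_mat(raw$stance, c("stance_R", "stance_L")),
    com = name_mat(raw$com, c("com_x", "com_y")),
    vcom = name_mat(raw$vcom, c("vcom_x", "vcom_y")),
    events = ev,
    work_pos = stats::setNames(raw$Wpos, colnames20),
    work_neg = stats::setNames(raw$Wneg, colnames20),
    distance = raw$distance,
    fell = raw$fell,
    fall_time = raw$fall_time,
    nonfinite = raw$nonfinite,
    t_end = raw$t_end,
    jgrf_brake = raw$jgrf_brake,
    dt = dt,
    record_dt = dt * record_every,
    total_mass = raw$total_mass,
    f_max = stats::setNames(rep(vapply(model$muscles, `[[`, 0, "f_max"), 2),
                            colnames20)
  ), class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("Gait trial: %.2f s simulated, %.2f m travelled%s\n",
              x$t_end, x$distance,
              if (x$fell) sprintf(", fell at %.2f s", x$fall_time) else ""))
  cat(sprintf("  %d samples at %.1f ms, %d contact events\n",
              length(x$time), 1000 * x$record_dt, nrow(x$events)))
  invisible(x)
}

#' Advance the dynamics by one or more fixed-activation steps
#'
#' Low-level stepping with constant muscle activations (no CPG), mainly for
#' testing the integrator.  Deterministic: identical inputs give bitwise
#' identical outputs.
#'
#' @param model an `msk_model`.
#' @param state list with `q`, `qd` (11 each) and optionally `phases`.
#' @param activations 20 activations in `[0, 1]` (right leg muscles 1-10,
#'   then left).
#' @param dt time step (s).
#' @param n number of steps.
#' @param options physics toggles (internal).
#' @return the advanced state (same shape as `state`).
#' @export
step_dynamics <- function(model, state, activations = rep(0, 20), dt = 1e-4,
                          n = 1L, options = .sim_options()) {
  stopifnot(dt > 0, length(state$q) == 11, length(state$qd) == 11)
  if (any(!is.finite(activations)) || any(activations < 0 | activations > 1))
    stop("activations must be within [0, 1]")
  phases <- if (is.null(state$phases)) c(0, pi) else state$phases
  ctrl <- list(type = "fixed", activations = as.numeric(activations))
  options$stop_on_fall <- FALSE
  raw <- .sim_run(model, ctrl, state$q, state$qd, phases,
                  n * dt, dt, n, options)
  if (raw$nonfinite)
    stop("integration produced a non-finite state at step ",
         round(raw$t_end / dt))
  list(q = as.numeric(raw$final_q), qd = as.numeric(raw$final_qd),
       phases = as.numeric(raw$final_phases))
}

#' Fixed-activation controller
#'
#' @param activations 20 constant activations (right leg muscles 1-10, then
#'   left leg).
#' @return controller object for [simulate_gait()].
#' @export
fixed_controller <- function(activations = rep(0, 20)) {
  stopifnot(length(activations) == 20)
  list(type = "fixed", activations = as.numeric(activations))
}

#' Passive joint moments (viscosity and knee stop)
#'
#' Linear viscous moments \eqn{-c \dot\theta} at every joint, plus the
#' nonlinear elastic knee stop \eqn{T = -k_1 \exp(-k_2 (k_3 - \theta))}
#' that resists knee hyperextension.
#'
#' @param model an `msk_model`.
#' @param q named joint angles (rad) for one leg (`hip`, `knee`, `ankle`,
#'   `mp`).
#' @param qd joint angular velocities (rad/s), same shape.
#' @return named vector of moments (N m) for one leg.
#' @export
passive_joint_moments <- function(model, q, qd = c(hip = 0, knee = 0,
                                                   ankle = 0, mp = 0)) {
  qq <- .leg_q(q)[JOINT_NAMES]
  qqd <- .leg_q(qd)[JOINT_NAMES]
  visc <- stats::setNames(model$joints$viscous_coefficient, model$joints$name)
  tau <- -visc[JOINT_NAMES] * qqd
  ks <- model$knee_stop
  tau["knee"] <- tau["knee"] - ks$k1 * exp(-ks$k2 * (ks$k3 - qq[["knee"]]))
  tau
}

#' Fall detection
#'
#' A state counts as fallen when the HAT centre of mass drops below a
#' fraction of its standing height, or the trunk pitch magnitude reaches the
#' configured limit (both boundaries closed).
#'
#' @param model an `msk_model`.
#' @param q generalized coordinates (11).
#' @param standing_hat_height reference HAT COM height (m); defaults to the
#'   height in the default standing posture.
#' @return logical flag.
#' @export
detect_fall <- function(model, q, standing_hat_height = NULL) {
  if (is.null(standing_hat_height)) {
    q0 <- default_init_state(model)$q
    standing_hat_height <- body_kinematics(model, q0)$com_y[1]
  }
  hat_y <- body_kinematics(model, q)$com_y[1]
  hat_y <= model$fall$height_frac * standing_hat_height ||
    abs(q[3]) >= model$fall$pitch_max
}

#' Whole-body kinematics at one state (R-side oracle)
#'
#' Positions, orientations and (optionally) velocities of all nine bodies,
#' computed independently of the compiled core.  Used for validation,
#' energy bookkeeping and COM checks.
#'
#' @param model an `msk_model`.
#' @param q generalized coordinates (11): hip x, hip y, pitch, right leg
#'   (hip, knee, ankle, mp), left leg.
#' @param qd generalized velocities (11), optional.
#' @return data.frame with one row per body (HAT, thigh/shank/foot/phalanges
#'   right then left): `psi`, `com_x`, `com_y`, `omega`, `vcom_x`, `vcom_y`,
#'   `mass`, `moi`.
#' @export
body_kinematics <- function(model, q, qd = rep(0, 11)) {
  segs <- model$segments
  base <- q[1:2]; vbase <- qd[1:2]
  out <- data.frame(body = c("HAT", paste0(rep(SEGMENT_NAMES[-1], 2), "_",
                                           rep(c("R", "L"), each = 4))),
                    psi = NA_real_, com_x = NA_real_, com_y = NA_real_,
                    omega = NA_real_, vcom_x = NA_real_, vcom_y = NA_real_,
                    mass = NA_real_, moi = NA_real_,
                    stringsAsFactors = FALSE)
  fill <- function(i, psi, com, omega, vcom, seg) {
    out$psi[i] <<- psi; out$com_x[i] <<- com[1]; out$com_y[i] <<- com[2]
    out$omega[i] <<- omega; out$vcom_x[i] <<- vcom[1]; out$vcom_y[i] <<- vcom[2]
    out$mass[i] <<- segs$mass[seg]; out$moi[i] <<- segs$moment_of_inertia[seg]
  }
  psi_hat <- pi / 2 - q[3]
  d <- segs$com_fraction[1] * segs$length[1] *
    c(cos(psi_hat), sin(psi_hat))
  fill(1, psi_hat, base + d, -qd[3], vbase + (-qd[3]) * .perp(d), 1)
  for (leg in 0:1) {
    qo <- 4 + 4 * leg
    psi <- psi_hat - pi
    omega <- -qd[3]
    p <- base; v <- vbase
    for (s in 1:4) {
      psi <- psi + q[qo + s - 1]
      omega <- omega + qd[qo + s - 1]
      seg <- s + 1
      cd <- segs$com_fraction[seg] * segs$length[seg] * c(cos(psi), sin(psi))
      fill(1 + 4 * leg + s, psi, p + cd, omega, v + omega * .perp(cd), seg)
      if (s < 4) {
        jd <- segs$length[seg] * c(cos(psi), sin(psi))
        v <- v + omega * .perp(jd)
        p <- p + jd
      }
    }
  }
  out
}

#' Mechanical energy of a state
#'
#' Kinetic plus gravitational potential energy of all nine bodies; the
#' independent bookkeeping used by the energy-conservation tests.
#'
#' @inheritParams body_kinematics
#' @return list with `kinetic`, `potential`, `total` (J).
#' @export
mechanical_energy <- function(model, q, qd) {
  bk <- body_kinematics(model, q, qd)
  ke <- sum(0.5 * bk$mass * (bk$vcom_x^2 + bk$vcom_y^2) +
              0.5 * bk$moi * bk$omega^2)
  pe <- sum(bk$mass * model$gravity * bk$com_y)
  list(kinetic = ke, potential = pe, total = ke + pe)
}
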