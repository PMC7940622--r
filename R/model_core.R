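# Musculoskeletal model: segments, joints, muscle routing, foot contact layout.
#
# Conventions (used throughout the package):
#  * World frame: x forward, y up, ground at y = 0.
#  * Generalized coordinates q (11): hip position (x, y), trunk pitch theta_HAT
#    (rad, positive = forward lean from vertical), then per leg (right leg
#    first, then left): hip, knee, ankle, metatarsophalangeal (MP) angles.
#  * Joint angle signs: positive for hip flexion, knee extension, ankle
#    dorsiflexion and MP dorsiflexion. Zero = adjacent segment long axes
#    aligned (limb fully extended in a straight line below the trunk).
#  * Segment long-axis world angles (counter-clockwise from +x):
#      psi_HAT   = pi/2 - pitch          (proximal end at the hip)
#      psi_thigh = psi_HAT - pi + q_hip
#      psi_shank = psi_thigh + q_knee
#      psi_foot  = psi_shank + q_ankle
#      psi_phal  = psi_foot  + q_mp
#  * Segment local frames: origin at the proximal joint, local x along the
#    long axis towards the distal end, local y the CCW normal. With the limb
#    hanging down, local +y on thigh/shank/foot/phalanges faces anterior;
#    on the HAT (axis pointing up), local +y faces posterior.

SEGMENT_NAMES <- c("HAT", "thigh", "shank", "foot", "phalanges")
JOINT_NAMES   <- c("hip", "knee", "ankle", "mp")
MUSCLE_NAMES  <- c("IL", "GMED", "VAS", "TA", "SOL",
                   "RF", "BIFl", "GAS", "EDL", "FDL")

# distal map: joints -> segments whose pose they affect
.joint_distal <- list(
  hip   = c("thigh", "shank", "foot", "phalanges"),
  knee  = c("shank", "foot", "phalanges"),
  ankle = c("foot", "phalanges"),
  mp    = "phalanges"
)

#' Build the default Japanese macaque musculoskeletal model
#'
#' Constructs the planar nine-link model: a lumped head-arms-trunk (HAT)
#' segment and two hindlimbs of thigh, shank, foot (tarsometatarsal part) and
#' phalanges, connected by hinge joints (hip, knee, ankle, MP).  Segment
#' inertial parameters, joint viscosities, the nonlinear knee hyperextension
#' stop, the muscle parameter table for the ten principal muscle groups, the
#' parallel passive-elastic (PE) muscle parameters and the eight-point
#' viscoelastic foot-ground contact layout all default to the published
#' macaque model constants.
#'
#' Muscle attachment coordinates (origin, via and insertion points in segment
#' local frames) are a calibrated planar stand-in for the anatomical 3D
#' routing, constructed so that each muscle's moment-arm sign matches its
#' anatomical action and magnitudes are a plausible fraction of segment
#' length; they are user-replaceable through the model config file.
#'
#' @param calibrate logical; if `TRUE` (default) muscle rest lengths are
#'   calibrated geometrically at the reference postures via
#'   [calibrate_rest_lengths()].
#' @return An object of class `msk_model`.
#' @export
build_default_model <- function(calibrate = TRUE) {
  segments <- data.frame(
    name              = SEGMENT_NAMES,
    mass              = c(8.184, 0.557, 0.269, 0.080, 0.021),
    length            = c(0.48, 0.163, 0.182, 0.074, 0.045),
    com_fraction      = c(0.52, 0.41, 0.40, 0.62, 0.50),
    moment_of_inertia = c(2.07e-2, 1.61e-3, 7.01e-4, 5.49e-5, 6.26e-6),
    stringsAsFactors  = FALSE
  )
  joints <- data.frame(
    name                = JOINT_NAMES,
    viscous_coefficient = c(0.109, 0.317, 0.0943, 0.01),
    stringsAsFactors    = FALSE
  )
  # nonlinear elastic knee stop T = -k1 * exp(-k2 * (k3 - theta_knee))
  knee_stop <- list(k1 = 1, k2 = 30, k3 = -0.23)
  # parallel elastic element f = k1_pe * (exp(k2_pe * (L - Lrest)) - 1)
  pe_params <- list(k1_pe = 26, k2_pe = 150, clamp_nonnegative = FALSE)

  muscles <- default_muscle_table()

  # 8 contact points per foot: 6 on the tarsometatarsal sole from the heel
  # (calcaneal tuberosity, posterior to the ankle) to the metatarsal head,
  # plus 2 under the phalangeal segment.
  sole_x <- seq(-0.020, 0.074, length.out = 6)
  layout <- data.frame(
    segment = c(rep("foot", 6), rep("phalanges", 2)),
    x = c(sole_x, 0.015, 0.040),
    y = c(rep(-0.008, 6), -0.005, -0.005),
    stringsAsFactors = FALSE
  )
  contact <- list(
    params = list(k_vert = 6000, c_vert = 60, k_horz = 1200, c_horz = 13,
                  grf_threshold = 1, debounce = 0.020),
    layout = layout,
    heel_index = 1L,
    heel_drop = 0
  )

  model <- structure(list(
    segments  = segments,
    joints    = joints,
    knee_stop = knee_stop,
    pe_params = pe_params,
    muscles   = muscles,
    contact   = contact,
    gravity   = 9.81,
    joint_ranges = list(hip = c(-0.3, 1.45), knee = c(-1.6, -0.2),
                        ankle = c(0.15, 1.75), mp = c(-0.5, 1.25)),
    fall      = list(height_frac = 0.5, pitch_max = pi / 2)
  ), class = "msk_model")

  if (calibrate) model <- calibrate_rest_lengths(model)
  model
}

# The published muscle table: maximum isometric forces and the reference
# postures (deg) at which each muscle is at its rest length.  rest_length_ref
# is the published rest length of the anatomical model, kept for reference;
# the operative rest_length is calibrated from the planar routing.
default_muscle_table <- function() {
  path <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(segment = SEGMENT_NAMES[as.numeric(m[, 1])],
               x = as.numeric(m[, 2]), y = as.numeric(m[, 3]),
               stringsAsFactors = FALSE)
  }
  spec <- list(
    list(name = "IL",   f_max = 642,  ref = 0.153,
         posture = c(hip = 80),
         path = path(1, 0.12, -0.020,  1, 0.02, -0.030,  2, 0.035, 0.008)),
    list(name = "GMED", f_max = 738,  ref = 0.086,
         posture = c(hip = 34),
         path = path(1, 0.04, 0.030,  1, 0.000, 0.038,  2, 0.03, -0.028,
                     2, 0.10, -0.026)),
    list(name = "VAS",  f_max = 2514, ref = 0.149,
         posture = c(knee = -45),
         path = path(2, 0.05, 0.015,  2, 0.155, 0.032,  3, 0.012, 0.030,
                     3, 0.045, 0.015)),
    list(name = "TA",   f_max = 390,  ref = 0.151,
         posture = c(ankle = 70),
         path = path(3, 0.05, 0.018,  3, 0.170, 0.015,  4, 0.025, 0.012)),
    list(name = "SOL",  f_max = 822,  ref = 0.159,
         posture = c(ankle = 70),
         path = path(3, 0.03, -0.012,  4, -0.025, 0.000)),
    list(name = "RF",   f_max = 720,  ref = 0.189,
         posture = c(hip = 25, knee = -45),
         path = path(1, 0.03, -0.030,  2, 0.155, 0.032,  3, 0.012, 0.030,
                     3, 0.045, 0.015)),
    list(name = "BIFl", f_max = 804,  ref = 0.196,
         posture = c(hip = 50, knee = -45),
         path = path(1, 0.015, 0.035,  1, 0.000, 0.034,  2, 0.05, -0.024,
                     3, 0.035, -0.015)),
    list(name = "GAS",  f_max = 720,  ref = 0.170,
         posture = c(knee = -65, ankle = 60),
         path = path(2, 0.145, -0.015,  4, -0.025, 0.000)),
    list(name = "EDL",  f_max = 140,  ref = 0.275,
         posture = c(ankle = 20, mp = 0),
         path = path(3, 0.04, 0.018,  3, 0.170, 0.015,  4, 0.040, 0.010,
                     4, 0.072, 0.008,  5, 0.025, 0.004)),
    list(name = "FDL",  f_max = 180,  ref = 0.224,
         posture = c(ankle = 40, mp = 0),
         path = path(3, 0.06, -0.014,  3, 0.176, -0.016,  4, 0.016, -0.013,
                     4, 0.072, -0.012,  5, 0.007, -0.012,  5, 0.032, -0.006))
  )
  lapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    joints_spanned <- names(s$posture)
    list(id = i, name = s$name, f_max = s$f_max,
         rest_length = NA_real_, rest_length_ref = s$ref,
         rest_posture = s$posture, spanned_joints = joints_spanned,
         path = s$path)
  })
}

# ---- forward kinematics -----------------------------------------------------

.rot <- function(psi) matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2, 2)
.perp <- function(v) c(-v[2], v[1])

# Segment world angles for one leg; q = c(pitch, hip, knee, ankle, mp)
segment_angles <- function(q) {
  q <- unname(q)
  psi_hat   <- pi / 2 - q[1]
  psi_thigh <- psi_hat - pi + q[2]
  psi_shank <- psi_thigh + q[3]
  psi_foot  <- psi_shank + q[4]
  psi_phal  <- psi_foot + q[5]
  c(HAT = psi_hat, thigh = psi_thigh, shank = psi_shank,
    foot = psi_foot, phalanges = psi_phal)
}

# Joint world positions for one leg with the hip at `base`.
joint_positions <- function(model, q, base = c(0, 0)) {
  psi <- segment_angles(q)
  len <- stats::setNames(model$segments$length, model$segments$name)
  hip   <- base
  knee  <- hip + len["thigh"] * c(cos(psi["thigh"]), sin(psi["thigh"]))
  ankle <- knee + len["shank"] * c(cos(psi["shank"]), sin(psi["shank"]))
  mp    <- ankle + len["foot"] * c(cos(psi["foot"]), sin(psi["foot"]))
  list(hip = hip, knee = knee, ankle = ankle, mp = mp, psi = psi)
}

# World position of a point given in a segment's local frame (one leg).
point_world <- function(model, segment, local, q, base = c(0, 0)) {
  jp <- joint_positions(model, q, base)
  origin <- switch(segment,
    HAT = jp$hip, thigh = jp$hip, shank = jp$knee,
    foot = jp$ankle, phalanges = jp$mp)
  origin + as.vector(.rot(jp$psi[[segment]]) %*% local)
}

# normalize a joint-angle query into c(pitch, hip, knee, ankle, mp) radians
.leg_q <- function(q) {
  out <- c(pitch = 0, hip = 0, knee = 0, ankle = 0, mp = 0)
  if (is.null(names(q))) {
    stopifnot(length(q) <= 5)
    out[seq_along(q)] <- q
  } else {
    bad <- setdiff(names(q), names(out))
    if (length(bad)) stop("unknown joint name(s): ", paste(bad, collapse = ", "))
    out[names(q)] <- q
  }
  out
}

#' Muscle path length at a posture
#'
#' Polyline length of a muscle's path (origin, via points, insertion)
#' positioned by forward kinematics.  Lengths depend only on the joint angles
#' the muscle spans.
#'
#' @param model an `msk_model`.
#' @param q named joint angles in radians (`hip`, `knee`, `ankle`, `mp`;
#'   unnamed entries are taken in the order pitch, hip, knee, ankle, mp).
#'   Missing joints default to 0.
#' @param muscle muscle name (e.g. `"SOL"`) or id (1-10); if `NULL`, a named
#'   vector of all ten lengths is returned.
#' @return length(s) in metres.
#' @export
muscle_length <- function(model, q, muscle = NULL) {
  qq <- .leg_q(q)
  one <- function(mus) {
    pts <- vapply(seq_len(nrow(mus$path)), function(i)
      point_world(model, mus$path$segment[i],
                  c(mus$path$x[i], mus$path$y[i]), qq),
      numeric(2))
    sum(sqrt(rowSums(diff(t(pts))^2)))
  }
  if (is.null(muscle)) {
    stats::setNames(vapply(model$muscles, one, numeric(1)),
                    vapply(model$muscles, `[[`, "", "name"))
  } else {
    one(.get_muscle(model, muscle))
  }
}

.get_muscle <- function(model, muscle) {
  if (is.character(muscle)) {
    i <- match(muscle, vapply(model$muscles, `[[`, "", "name"))
    if (is.na(i)) stop("unknown muscle: ", muscle)
    model$muscles[[i]]
  } else model$muscles[[muscle]]
}

#' Muscle moment arm about a joint
#'
#' Returns \eqn{-\partial L_m/\partial\theta_j}, the moment arm of a muscle
#' about a joint under the package's sign convention: a positive moment arm
#' means muscle tension produces a positive joint moment (hip flexion, knee
#' extension, ankle/MP dorsiflexion).  Joints not spanned by the muscle
#' return 0.
#'
#' @inheritParams muscle_length
#' @param joint one of `"hip"`, `"knee"`, `"ankle"`, `"mp"`.
#' @return moment arm in metres.
#' @export
moment_arm <- function(model, q, muscle, joint) {
  joint <- match.arg(joint, JOINT_NAMES)
  mus <- .get_muscle(model, muscle)
  if (!(joint %in% mus$spanned_joints)) return(0)
  qq <- .leg_q(q)
  jp <- joint_positions(model, qq)
  pivot <- jp[[joint]]
  distal <- .joint_distal[[joint]]
  pts <- lapply(seq_len(nrow(mus$path)), function(i)
    point_world(model, mus$path$segment[i],
                c(mus$path$x[i], mus$path$y[i]), qq))
  dpts <- lapply(seq_len(nrow(mus$path)), function(i) {
    if (mus$path$segment[i] %in% distal) .perp(pts[[i]] - pivot) else c(0, 0)
  })
  dL <- 0
  for (i in seq_len(length(pts) - 1)) {
    seg <- pts[[i + 1]] - pts[[i]]
    u <- seg / sqrt(sum(seg^2))
    dL <- dL + sum(u * (dpts[[i + 1]] - dpts[[i]]))
  }
  -dL
}

#' Calibrate muscle rest lengths at their reference postures
#'
#' Sets each muscle's rest length to its geometric path length evaluated at
#' the published reference posture (e.g. SOL at 70 degrees ankle dorsiflexion,
#' GAS at knee -65 / ankle 60).  At that posture the PE element force is then
#' exactly zero.
#'
#' @param model an `msk_model`.
#' @return the model with `rest_length` filled in for every muscle.
#' @export
calibrate_rest_lengths <- function(model) {
  for (i in seq_along(model$muscles)) {
    mus <- model$muscles[[i]]
    q <- mus$rest_posture * pi / 180
    for (j in names(q)) {
      r <- model$joint_ranges[[j]]
      if (q[[j]] < r[1] - 1e-9 || q[[j]] > r[2] + 1e-9)
        stop("rest posture of ", mus$name, " outside ", j, " joint range")
    }
    model$muscles[[i]]$rest_length <- muscle_length(model, q, mus$name)
  }
  model
}

#' Translate the heel contact point inferiorly (digitigrade to plantigrade)
#'
#' Lowers the most posterior contact point of each foot (the calcaneal
#' tuberosity) by `drop` metres along the foot's local inferior (plantar)
#' direction.  The operation is absolute with respect to the default layout
#' (applying 10 mm twice gives 10 mm, not 20), and changes nothing but that
#' one contact coordinate per foot: inertial parameters and muscle routing
#' are untouched.
#'
#' @param model an `msk_model`.
#' @param drop inferior translation in metres, between 0 and `max_drop`.
#' @param max_drop range cap (default 0.036 m, the full human-like heel).
#' @return the morphed model with `contact$heel_drop = drop`.
#' @export
apply_heel_translation <- function(model, drop, max_drop = 0.036) {
  if (!is.finite(drop) || drop < 0 || drop > max_drop)
    stop("heel drop must be within [0, ", max_drop, "] m")
  i <- model$contact$heel_index
  base_y <- model$contact$layout$y[i] + model$contact$heel_drop
  model$contact$layout$y[i] <- base_y - drop
  model$contact$heel_drop <- drop
  model
}

#' Validate a musculoskeletal model
#'
#' Checks type invariants (positive masses, lengths, inertias, COM fractions
#' in range, non-negative joint viscosities), the contact layout (8 points,
#' heel most posterior), calibrated rest lengths, and that every muscle's
#' moment-arm sign at its reference posture matches its anatomical action.
#'
#' @param model an `msk_model`.
#' @return character vector of violations; empty if the model is valid.
#' @export
validate_model <- function(model) {
  v <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) v <<- c(v, msg)
  s <- model$segments
  chk(all(s$mass > 0), "segment mass > 0")
  chk(all(s$length > 0), "segment length > 0")
  chk(all(s$com_fraction >= 0 & s$com_fraction <= 1), "com_fraction in [0,1]")
  chk(all(s$moment_of_inertia > 0), "moment_of_inertia > 0")
  chk(all(model$joints$viscous_coefficient >= 0), "joint viscosity >= 0")
  lay <- model$contact$layout
  chk(nrow(lay) == 8, "contact layout has 8 points")
  foot_pts <- which(lay$segment == "foot")
  hi <- model$contact$heel_index
  chk(hi %in% foot_pts && all(lay$x[hi] <= lay$x[foot_pts]),
      "heel point is the most posterior sole point")
  chk(model$contact$heel_drop >= 0, "heel_drop >= 0")
  # anatomical moment-arm signs at each muscle's reference posture
  action <- list(
    IL   = c(hip =  1),
    GMED = c(hip = -1),
    VAS  = c(knee = 1),
    TA   = c(ankle = 1),
    SOL  = c(ankle = -1),
    RF   = c(hip = 1, knee = 1),
    BIFl = c(hip = -1, knee = -1),
    GAS  = c(knee = -1, ankle = -1),
    EDL  = c(ankle = 1, mp = 1),
    FDL  = c(ankle = -1, mp = -1)
  )
  for (mus in model$muscles) {
    chk(is.finite(mus$f_max) && mus$f_max > 0,
        paste0(mus$name, ": f_max > 0"))
    chk(nrow(mus$path) >= 2, paste0(mus$name, ": path has >= 2 points"))
    if (is.finite(mus$rest_length))
      chk(mus$rest_length > 0, paste0(mus$name, ": rest_length > 0"))
    q <- mus$rest_posture * pi / 180
    for (j in names(action[[mus$name]])) {
      ma <- moment_arm(model, q, mus$name, j)
      chk(sign(ma) == action[[mus$name]][[j]],
          paste0(mus$name, ": moment arm sign at ", j))
    }
  }
  chk(abs(total_mass(model) - (s$mass[1] + 2 * sum(s$mass[-1]))) < 1e-12,
      "total mass = HAT + 2 x limb masses")
  v
}

#' Total body mass of the model
#'
#' HAT plus both (mirrored) limbs.
#' @param model an `msk_model`.
#' @return mass in kg.
#' @export
total_mass <- function(model) {
  m <- model$segments$mass
  m[1] + 2 * sum(m[-1])
}

# ---- config I/O -------------------------------------------------------------

#' Write / read a model configuration file
#'
#' Serializes the full model (segments, joints, knee stop, PE parameters,
#' muscles with attachment paths, contact layout, gravity) to a YAML file in
#' SI units.  `read_model_config()` round-trips losslessly.
#'
#' @param model an `msk_model`.
#' @param path file path.
#' @return `read_model_config` returns an `msk_model`.
#' @export
write_model_config <- function(model, path) {
  obj <- unclass(model)
  obj$segments <- as.list(obj$segments)
  obj$joints <- as.list(obj$joints)
  obj$contact$layout <- as.list(obj$contact$layout)
  obj$muscles <- lapply(obj$muscles, function(m) {
    m$path <- as.list(m$path)
    m$rest_posture <- as.list(m$rest_posture)
    m
  })
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$segments <- as.data.frame(obj$segments, stringsAsFactors = FALSE)
  obj$joints <- as.data.frame(obj$joints, stringsAsFactors = FALSE)
  obj$contact$layout <- as.data.frame(obj$contact$layout,
                                      stringsAsFactors = FALSE)
  obj$contact$heel_index <- as.integer(obj$contact$heel_index)
  obj$muscles <- lapply(obj$muscles, function(m) {
    m$path <- as.data.frame(m$path, stringsAsFactors = FALSE)
    m$rest_posture <- unlist(m$rest_posture)
    m$spanned_joints <- unlist(m$spanned_joints)
    m
  })
  structure(obj, class = "msk_model")
}

#' @export
print.msk_model <- function(x, ...) {
  cat("Planar macaque musculoskeletal model\n")
  cat(sprintf("  %d segments (total mass %.3f kg), %d muscles/leg\n",
              nrow(x$segments), total_mass(x), length(x$muscles)))
  cat(sprintf("  heel drop: %.1f mm\n", 1000 * x$contact$heel_drop))
  invisible(x)
}
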