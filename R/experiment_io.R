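# Gait metrics, GRF profile classification, the heel-morphing experiment
# pipeline, synthetic fixture gaits, and trial import/export.

#' Stride-averaged gait metrics
#'
#' Metrics are computed on steady strides: right-leg touchdowns define
#' cycles, the first `transient_strides` cycles are discarded, and at least
#' `min_strides` complete cycles must remain.  Cycle duration is the mean
#' touchdown-to-touchdown interval; stride length is COM travel per cycle;
#' the duty factor is stance duration over cycle duration, averaged over
#' both legs; speed is COM travel over elapsed time in the analysis window.
#' COT uses the whole-trial work accumulators; %recovery is evaluated over
#' the integer-stride analysis window.
#'
#' @param trial a `gait_trial`.
#' @param transient_strides cycles discarded from the start (default 2).
#' @param min_strides minimum complete cycles required after the discard.
#' @param ... energetics calibration passed to [cost_of_transport()].
#' @return list of class `gait_summary`.
#' @export
gait_metrics <- function(trial, transient_strides = 2, min_strides = 3, ...) {
  evR <- trial$events[trial$events$leg == "R", ]
  td <- evR$time[evR$type == "touchdown"]
  if (length(td) < transient_strides + min_strides + 1)
    stop("insufficient steady strides (need >= ", min_strides,
         " after discarding ", transient_strides, ")")
  td <- td[-seq_len(transient_strides)]
  n_cycles <- length(td) - 1
  cycle <- mean(diff(td))
  idx <- function(t) which.min(abs(trial$time - t))
  x0 <- unname(trial$com[idx(td[1]), "com_x"])
  x1 <- unname(trial$com[idx(td[length(td)]), "com_x"])
  stride <- (x1 - x0) / n_cycles
  speed <- (x1 - x0) / (td[length(td)] - td[1])
  duty <- .window_duty(trial, td[1], td[length(td)])
  win <- trial$time >= td[1] & trial$time <= td[length(td)]
  ce <- com_energy(trial)
  recovery <- percent_recovery(ce[win, ])
  cot <- tryCatch(cost_of_transport(trial, ...), error = function(e) NA_real_)
  prof <- classify_grf_profile(trial, transient_strides = transient_strides)
  structure(list(cycle_duration = cycle, stride_length = stride,
                 speed = speed, duty_factor = duty,
                 cot = cot, percent_recovery = recovery,
                 grf_profile = prof$profile, grf_peaks = prof$n_peaks,
                 n_strides = n_cycles), class = "gait_summary")
}

.window_duty <- function(trial, t0, t1) {
  duties <- c()
  for (lg in c("R", "L")) {
    ev <- trial$events[trial$events$leg == lg, ]
    td <- ev$time[ev$type == "touchdown"]
    td <- td[td >= t0 - 1e-9 & td <= t1 + 1e-9]
    if (length(td) < 2) next
    for (i in seq_len(length(td) - 1)) {
      cyc <- td[i + 1] - td[i]
      to <- ev$time[ev$type == "toeoff" & ev$time > td[i] &
                      ev$time < td[i + 1]]
      if (length(to) == 1 && cyc > 0) duties <- c(duties, (to - td[i]) / cyc)
    }
  }
  if (length(duties)) mean(duties) else NA_real_
}

#' @export
print.gait_summary <- function(x, ...) {
  cat(sprintf(paste0("Gait summary (%d strides): cycle %.3f s, stride %.3f",
                     " m, speed %.3f m/s\n  duty factor %.3f, COT %.2f",
                     " J/(kg m), recovery %.1f%%, GRF %s-peaked\n"),
              x$n_strides, x$cycle_duration, x$stride_length, x$speed,
              x$duty_factor, x$cot, x$percent_recovery, x$grf_profile))
  invisible(x)
}

#' Classify the vertical GRF profile as single- or double-peaked
#'
#' Builds the stride-averaged right-leg vertical GRF over the stance phase
#' (each stance resampled to 0-100%, averaged over steady cycles), excludes
#' the initial impact transient (first `impact_frac` of stance, where the
#' penalty contact produces an instantaneous force spike), and counts local
#' maxima with prominence of at least `prominence_frac` of the profile peak.
#' One qualifying maximum is a single-peaked profile; two or more,
#' double-peaked.
#'
#' @param trial a `gait_trial`.
#' @param transient_strides cycles discarded from the start.
#' @param impact_frac fraction of stance excluded at touchdown (default
#'   0.05).
#' @param prominence_frac peak prominence threshold as a fraction of the
#'   profile maximum (default 0.05).
#' @return list with `profile` (`"single"`, `"double"` or `"none"`),
#'   `n_peaks`, and the stance-normalized mean curve (`pct`, `grf`).
#' @export
classify_grf_profile <- function(trial, transient_strides = 2,
                                 impact_frac = 0.05,
                                 prominence_frac = 0.05) {
  ev <- trial$events[trial$events$leg == "R", ]
  td <- ev$time[ev$type == "touchdown"]
  if (length(td) > transient_strides) td <- td[-seq_len(transient_strides)]
  pct <- seq(0, 100, length.out = 201)
  curves <- list()
  for (t0 in td) {
    to <- ev$time[ev$type == "toeoff" & ev$time > t0]
    if (!length(to)) next
    t1 <- to[1]
    win <- trial$time >= t0 & trial$time <= t1
    if (sum(win) < 5) next
    s <- (trial$time[win] - t0) / (t1 - t0) * 100
    curves[[length(curves) + 1]] <-
      stats::approx(s, trial$grf[win, "vert_R"], xout = pct, rule = 2)$y
  }
  if (!length(curves))
    return(list(profile = "none", n_peaks = 0L,
                curve = data.frame(pct = pct, grf = rep(0, length(pct)))))
  avg <- colMeans(do.call(rbind, curves))
  keep <- pct >= 100 * impact_frac
  y <- avg[keep]
  pk <- pracma::findpeaks(y, minpeakheight = 0,
                          minpeakdistance = 10, zero = "0")
  n <- 0L
  if (!is.null(pk)) {
    prom <- apply(pk, 1, function(p) {
      i <- p[2]; lo <- min(y[max(1, p[3]):i]); hi <- min(y[i:p[4]])
      p[1] - max(lo, hi)
    })
    n <- sum(prom >= prominence_frac * max(y))
  }
  profile <- if (n >= 2) "double" else if (n == 1) "single" else "none"
  list(profile = profile, n_peaks = as.integer(n),
       curve = data.frame(pct = pct, grf = avg))
}

#' Synthetic walking trial generator
#'
#' Builds a kinematically consistent synthetic gait trial (periodic contact
#' events, square-ish per-leg vertical GRF with a configurable single- or
#' double-peaked stance shape, and a COM trajectory whose potential/kinetic
#' energies are anti-phase (`recovery = "pendular"`) or in phase
#' (`recovery = "inphase"`)), so the analysis layer can be exercised without
#' running the optimizer.  Seeded and deterministic.
#'
#' @param seed integer seed.
#' @param cycle gait cycle duration (s).
#' @param duty_factor stance fraction of the cycle.
#' @param speed mean forward speed (m/s).
#' @param n_strides number of full strides.
#' @param grf_shape `"single"` or `"double"` peaked stance profile.
#' @param recovery `"pendular"` (out-of-phase energies) or `"inphase"`.
#' @param com_height,com_amplitude mean COM height and vertical oscillation
#'   amplitude (m).
#' @param peak_force stance profile peak (N).
#' @param noise_sd additive GRF noise (N).
#' @param dt sample interval (s).
#' @param mass body mass (kg).
#' @return a `gait_trial`-compatible object.
#' @export
make_fixture_gait <- function(seed = 1, cycle = 0.72, duty_factor = 0.65,
                              speed = 1.0, n_strides = 8,
                              grf_shape = c("single", "double"),
                              recovery = c("pendular", "inphase"),
                              com_height = 0.45, com_amplitude = 0.008,
                              peak_force = 110, noise_sd = 0, dt = 0.002,
                              mass = 10.038) {
  grf_shape <- match.arg(grf_shape)
  recovery <- match.arg(recovery)
  set.seed(seed)
  t_end <- (n_strides + 1) * cycle
  time <- seq(0, t_end, by = dt)
  n <- length(time)
  stance_dur <- duty_factor * cycle
  shape <- function(s) {
    if (grf_shape == "single") sin(pi * s)
    else exp(-(s - 0.28)^2 / (2 * 0.006)) + exp(-(s - 0.75)^2 / (2 * 0.006)) +
      0.3 * sin(pi * s)
  }
  leg_grf <- function(offset) {
    g <- numeric(n)
    td <- seq(offset, t_end, by = cycle)
    for (t0 in td) {
      s <- (time - t0) / stance_dur
      in_st <- s >= 0 & s <= 1
      g[in_st] <- g[in_st] + shape(s[in_st])
    }
    g * peak_force / max(shape(seq(0.01, 0.99, 0.01)))
  }
  grfR <- leg_grf(0); grfL <- leg_grf(cycle / 2)
  if (noise_sd > 0) {
    grfR <- pmax(0, grfR + stats::rnorm(n, 0, noise_sd) * (grfR > 0))
    grfL <- pmax(0, grfL + stats::rnorm(n, 0, noise_sd) * (grfL > 0))
  }
  # COM: vertical oscillation at twice the cycle frequency (one per step);
  # kinetic energy set anti-phase (pendular) or in phase with potential
  omega <- 2 * pi / (cycle / 2)
  y <- com_height + com_amplitude * sin(omega * time)
  vy <- com_amplitude * omega * cos(omega * time)
  g <- 9.81
  Ek_mean <- 0.5 * mass * speed^2
  swing <- mass * g * com_amplitude
  phase_sign <- if (recovery == "pendular") -1 else 1
  Ek_x <- pmax(Ek_mean + phase_sign * swing * sin(omega * time) -
                 0.5 * mass * vy^2, 0.01)
  vx <- sqrt(2 * Ek_x / mass)
  vx <- vx * speed / mean(vx)   # exact mean forward speed
  x <- cumsum(c(0, (vx[-1] + vx[-n]) / 2 * dt))
  events <- data.frame(time = numeric(0), leg = character(0),
                       type = character(0), stringsAsFactors = FALSE)
  for (lg in c("R", "L")) {
    off <- if (lg == "R") 0 else cycle / 2
    td <- seq(off, t_end, by = cycle)
    to <- td + stance_dur
    events <- rbind(events,
                    data.frame(time = td, leg = lg, type = "touchdown",
                               stringsAsFactors = FALSE),
                    data.frame(time = to[to <= t_end], leg = lg,
                               type = "toeoff", stringsAsFactors = FALSE))
  }
  events <- events[order(events$time), ]
  rownames(events) <- NULL
  mn <- c(paste0(MUSCLE_NAMES, "_R"), paste0(MUSCLE_NAMES, "_L"))
  zeros20 <- matrix(0, n, 20, dimnames = list(NULL, mn))
  q <- matrix(0, n, 11,
              dimnames = list(NULL, c("x", "y", "pitch",
                                      paste0(JOINT_NAMES, "_R"),
                                      paste0(JOINT_NAMES, "_L"))))
  q[, "x"] <- x; q[, "y"] <- y
  structure(list(
    time = time, q = q,
    qd = matrix(0, n, 11), phases = matrix(0, n, 2),
    act = zeros20, f_total = zeros20, f_active = zeros20, f_pe = zeros20,
    muscle_len = matrix(0.15, n, 20, dimnames = list(NULL, mn)),
    grf = cbind(vert_R = grfR, horz_R = 0, vert_L = grfL, horz_L = 0),
    cop = cbind(cop_R = rep(NA_real_, n), cop_L = NA_real_),
    stance = cbind(stance_R = as.numeric(grfR > 1),
                   stance_L = as.numeric(grfL > 1)),
    com = cbind(com_x = x, com_y = y),
    vcom = cbind(vcom_x = vx, vcom_y = vy),
    events = events,
    work_pos = stats::setNames(rep(0, 20), mn),
    work_neg = stats::setNames(rep(0, 20), mn),
    distance = x[n], fell = FALSE, fall_time = NA_real_,
    nonfinite = FALSE, t_end = t_end, jgrf_brake = 0,
    dt = dt, record_dt = dt, total_mass = mass,
    f_max = stats::setNames(rep(c(642, 738, 2514, 390, 822, 720, 804, 720,
                                  140, 180), 2), mn)
  ), class = "gait_trial")
}

# ---- heel-morphing experiment ----------------------------------------------

#' Run the virtual foot-morphing experiment
#'
#' For each heel drop in the schedule: morph the model with
#' [apply_heel_translation()], re-optimize the activation patterns with the
#' GA warm-started from the previous step's best genome, and record the gait
#' summary.  A step whose best gait does not exceed the objective's switch
#' distance is recorded as failed (`NA` metrics) and the pipeline continues
#' with the previous warm start.  When `out_dir` is given, per-step genomes
#' and summaries are written there and already-completed steps are loaded
#' instead of recomputed (resumability).
#'
#' @param model the unmorphed `msk_model`.
#' @param config a [ga_config()].
#' @param schedule increasing heel drops in metres (default 0 to 0.036 by
#'   1 mm).
#' @param warm_start optional genome for the first step.
#' @param seed integer seed; step i uses `seed + i` for its GA run.
#' @param out_dir optional directory for run artifacts.
#' @param verbose print progress.
#' @return list of class `morph_result`: `summary` data.frame and `genomes`.
#' @export
run_morph_experiment <- function(model, config = ga_config(),
                                 schedule = seq(0, 0.036, by = 0.001),
                                 warm_start = NULL, seed = 1,
                                 out_dir = NULL, verbose = FALSE) {
  stopifnot(!is.unsorted(schedule), all(schedule <= 0.036), all(schedule >= 0))
  rows <- list(); genomes <- list()
  prev <- warm_start
  for (i in seq_along(schedule)) {
    drop <- schedule[i]
    tag <- sprintf("heel_%03.0fmm", 1000 * drop)
    gfile <- if (!is.null(out_dir)) file.path(out_dir,
                                              paste0(tag, "_genome.txt"))
    if (!is.null(out_dir) && file.exists(gfile)) {
      best <- read_genome(gfile)
      if (verbose) message(tag, ": loaded existing result")
    } else {
      md <- apply_heel_translation(model, drop)
      ga <- ga_optimize(md, config, warm_start = prev, seed = seed + i)
      best <- ga$best_genome
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_genome(best, gfile)
      }
      if (verbose) message(sprintf("%s: best J %.3f, D %.1f m", tag,
                                   ga$best_J, ga$best_distance))
    }
    md <- apply_heel_translation(model, drop)
    ev <- evaluate_candidate(best, md, config, return_trial = TRUE)
    sm <- tryCatch(gait_metrics(ev$trial,
                                basal_rate = config$objective$basal_rate,
                                eta_pos = config$objective$eta_pos,
                                eta_neg = config$objective$eta_neg),
                   error = function(e) NULL)
    ok <- ev$distance > config$objective$switch_distance && !is.null(sm)
    rows[[i]] <- data.frame(
      heel_drop = drop, success = ok, J = ev$J, distance = ev$distance,
      cycle_duration = if (ok) sm$cycle_duration else NA_real_,
      stride_length = if (ok) sm$stride_length else NA_real_,
      speed = if (ok) sm$speed else NA_real_,
      duty_factor = if (ok) sm$duty_factor else NA_real_,
      cot = if (ok) sm$cot else NA_real_,
      percent_recovery = if (ok) sm$percent_recovery else NA_real_,
      grf_profile = if (ok) sm$grf_profile else NA_character_,
      stringsAsFactors = FALSE)
    genomes[[i]] <- best
    if (ok || !is.null(warm_start) || i == 1) prev <- if (ok) best else prev
  }
  summary <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(summary, file.path(out_dir, "morph_summary.csv"),
                     row.names = FALSE)
  structure(list(summary = summary, genomes = genomes,
                 schedule = schedule), class = "morph_result")
}

# ---- trial I/O --------------------------------------------------------------

#' Write / read a gait trial as CSV
#'
#' One row per recorded step with time, generalized coordinates and
#' velocities, oscillator phases, activations, muscle forces (total, active,
#' PE), muscle lengths, per-leg GRFs, COP, stance flags and COM kinematics.
#' Scalar metadata (distance, work accumulators, mass, ...) is stored in
#' `# key: value` header lines so the round trip is lossless; contact events
#' go to a separate table via `events_path`.
#'
#' @param trial a `gait_trial`.
#' @param path CSV path.
#' @param events_path optional path for the events table (default:
#'   `<path>` with `_events.csv` suffix).
#' @return `read_trial_csv` returns the reconstructed `gait_trial`.
#' @export
write_trial_csv <- function(trial, path,
                            events_path = sub("\\.csv$", "_events.csv", path)) {
  mn <- c(paste0(MUSCLE_NAMES, "_R"), paste0(MUSCLE_NAMES, "_L"))
  canon <- list(
    q = c("x", "y", "pitch", paste0(JOINT_NAMES, "_R"),
          paste0(JOINT_NAMES, "_L")),
    qd = c("vx", "vy", "pitch_rate", paste0(JOINT_NAMES, "_R_rate"),
           paste0(JOINT_NAMES, "_L_rate")),
    phases = c("phi_R", "phi_L"), act = mn, f_total = mn, f_active = mn,
    f_pe = mn, muscle_len = mn,
    grf = c("vert_R", "horz_R", "vert_L", "horz_L"),
    cop = c("cop_R", "cop_L"), stance = c("stance_R", "stance_L"),
    com = c("com_x", "com_y"), vcom = c("vcom_x", "vcom_y"))
  for (f in names(canon)) colnames(trial[[f]]) <- canon[[f]]
  df <- data.frame(time = trial$time, trial$q, trial$qd, trial$phases,
                   trial$act, f_tot = trial$f_total, f_act = trial$f_active,
                   f_pe = trial$f_pe, len = trial$muscle_len, trial$grf,
                   trial$cop, trial$stance, trial$com, trial$vcom,
                   check.names = TRUE)
  meta <- c(distance = trial$distance, fell = as.numeric(trial$fell),
            fall_time = ifelse(is.na(trial$fall_time), -1, trial$fall_time),
            nonfinite = as.numeric(trial$nonfinite), t_end = trial$t_end,
            jgrf_brake = trial$jgrf_brake, dt = trial$dt,
            record_dt = trial$record_dt, total_mass = trial$total_mass,
            stats::setNames(trial$work_pos,
                            paste0("Wpos_", names(trial$work_pos))),
            stats::setNames(trial$work_neg,
                            paste0("Wneg_", names(trial$work_neg))),
            stats::setNames(trial$f_max, paste0("fmax_", names(trial$f_max))))
  con <- file(path, "w")
  writeLines(sprintf("# %s: %.17g", names(meta), meta), con)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  close(con)
  utils::write.csv(trial$events, events_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path,
                           events_path = sub("\\.csv$", "_events.csv", path)) {
  lines <- readLines(path)
  hdr <- grepl("^# ", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- strsplit(sub("^# ", "", l), ": ")[[1]]
    meta[[kv[1]]] <- as.numeric(kv[2])
  }
  df <- utils::read.csv(text = paste(lines[!hdr], collapse = "\n"))
  events <- if (file.exists(events_path)) {
    ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
    if (!nrow(ev)) data.frame(time = numeric(0), leg = character(0),
                              type = character(0)) else ev
  } else data.frame(time = numeric(0), leg = character(0),
                    type = character(0))
  mn <- c(paste0(MUSCLE_NAMES, "_R"), paste0(MUSCLE_NAMES, "_L"))
  grab <- function(prefix, names) {
    m <- as.matrix(df[, paste0(prefix, names), drop = FALSE])
    colnames(m) <- names
    m
  }
  pick <- function(key, names) {
    stats::setNames(as.numeric(meta[paste0(key, "_", names)]), names)
  }
  qn <- c("x", "y", "pitch", paste0(JOINT_NAMES, "_R"),
          paste0(JOINT_NAMES, "_L"))
  qdn <- c("vx", "vy", "pitch_rate", paste0(JOINT_NAMES, "_R_rate"),
           paste0(JOINT_NAMES, "_L_rate"))
  structure(list(
    time = df$time,
    q = grab("", qn), qd = grab("", qdn),
    phases = grab("", c("phi_R", "phi_L")),
    act = grab("", mn), f_total = grab("f_tot.", mn),
    f_active = grab("f_act.", mn), f_pe = grab("f_pe.", mn),
    muscle_len = grab("len.", mn),
    grf = grab("", c("vert_R", "horz_R", "vert_L", "horz_L")),
    cop = grab("", c("cop_R", "cop_L")),
    stance = grab("", c("stance_R", "stance_L")),
    com = grab("", c("com_x", "com_y")),
    vcom = grab("", c("vcom_x", "vcom_y")),
    events = events,
    work_pos = pick("Wpos", mn), work_neg = pick("Wneg", mn),
    distance = meta$distance, fell = meta$fell > 0,
    fall_time = if (meta$fall_time < 0) NA_real_ else meta$fall_time,
    nonfinite = meta$nonfinite > 0, t_end = meta$t_end,
    jgrf_brake = meta$jgrf_brake, dt = meta$dt, record_dt = meta$record_dt,
    total_mass = meta$total_mass, f_max = pick("fmax", mn)
  ), class = "gait_trial")
}

#' Write a gait summary (or morph summary) as JSON
#'
#' @param x a `gait_summary`, `morph_result` or plain list.
#' @param path output path.
#' @export
write_summary_json <- function(x, path) {
  if (inherits(x, "morph_result")) x <- x$summary
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
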