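# Gait optimization: the composite locomotor objective and a seeded
# real-coded genetic algorithm over the 60-parameter pattern genome.

#' Objective configuration
#'
#' Weights and targets of the composite objective.  Below the switch
#' distance only the distance term is active (scaled by 1000), which makes
#' the early search maximize distance before shaping the gait; past it the
#' full weighted sum applies.
#'
#' @param weights six weights for the distance, cycle, HAT, energy, joint and
#'   GRF terms.
#' @param duty_target target duty factor.
#' @param switch_distance distance (m) separating the two objective regimes.
#' @param ref_touchdown reference joint angles (rad) at touchdown for the
#'   joint-angle term; a nominal macaque bipedal touchdown posture,
#'   user-replaceable.
#' @param basal_rate,eta_pos,eta_neg energetics calibration, see
#'   [energy_budget()].
#' @return list of class `objective_config`.
#' @export
objective_config <- function(weights = c(10, 1, 0.01, 0.1, 1, 1),
                             duty_target = 0.65, switch_distance = 9,
                             ref_touchdown = c(hip = 0.87, knee = -0.87,
                                               ankle = 1.05, mp = 0.52),
                             basal_rate = 2.0, eta_pos = 0.25,
                             eta_neg = 1.2) {
  stopifnot(length(weights) == 6)
  structure(list(weights = weights, duty_target = duty_target,
                 switch_distance = switch_distance,
                 ref_touchdown = ref_touchdown, basal_rate = basal_rate,
                 eta_pos = eta_pos, eta_neg = eta_neg),
            class = "objective_config")
}

# duty factor over all complete stance phases of both legs; NA if none
.mean_duty <- function(trial) {
  duties <- c()
  for (lg in c("R", "L")) {
    ev <- trial$events[trial$events$leg == lg, ]
    td <- ev$time[ev$type == "touchdown"]
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

#' Composite gait objective
#'
#' Distance-only regime when the travelled distance D is at or below the
#' switch distance (closed boundary): `J = 1000 / D`.  Beyond it,
#' `J = w1/D + w2 (duty - target)^2 + w3 var(pitch) + w4 COT + w5 Jjoint +
#' w6 Jgrf` where `Jjoint` is the mean squared error of the leg's joint
#' angles against the reference touchdown posture at each touchdown event,
#' and `Jgrf` integrates braking horizontal force on the phalangeal contact
#' points during the second half of the leg's oscillator cycle, normalized
#' by body weight times the gait period.
#'
#' @param trial a `gait_trial`.
#' @param config an [objective_config()].
#' @param cpg_T gait period (s) used to normalize the GRF term.
#' @return list with `J` and the individual `terms`.
#' @export
gait_objective <- function(trial, config = objective_config(),
                           cpg_T = 0.747) {
  D <- trial$distance
  if (D <= config$switch_distance) {
    J <- 1000 / max(D, 1e-3)  # large finite penalty as D -> 0
    return(list(J = J, terms = list(J_distance = 1 / max(D, 1e-3),
                                    regime = "distance")))
  }
  w <- config$weights
  J_distance <- 1 / D
  duty <- .mean_duty(trial)
  J_cycle <- if (is.na(duty)) 0.42 else (duty - config$duty_target)^2
  J_HAT <- stats::var(trial$q[, "pitch"])
  J_energy <- cost_of_transport(trial, basal_rate = config$basal_rate,
                                eta_pos = config$eta_pos,
                                eta_neg = config$eta_neg)
  # joint-angle error at touchdowns
  ref <- config$ref_touchdown
  errs <- c()
  for (i in seq_len(nrow(trial$events))) {
    if (trial$events$type[i] != "touchdown") next
    k <- which.min(abs(trial$time - trial$events$time[i]))
    cols <- paste0(names(ref), "_", trial$events$leg[i])
    errs <- c(errs, (trial$q[k, cols] - ref)^2)
  }
  J_joint <- if (length(errs)) mean(errs) else 0.4
  J_GRF <- trial$jgrf_brake / (trial$total_mass * 9.81 * cpg_T)
  terms <- list(J_distance = J_distance, J_cycle = J_cycle, J_HAT = J_HAT,
                J_energy = J_energy, J_joint = J_joint, J_GRF = J_GRF,
                duty = duty, regime = "full")
  J <- w[1] * J_distance + w[2] * J_cycle + w[3] * J_HAT +
    w[4] * J_energy + w[5] * J_joint + w[6] * J_GRF
  list(J = J, terms = terms)
}

#' Per-gene bounds of the pattern genome
#'
#' gamma and delta in `[0, 1]`, peak timings in `[0, 2pi)`, width parameters
#' in `[0.01, 2]` rad^2 (preventing degenerate spikes and flats).
#'
#' @return a 60 x 2 matrix (lower, upper) in genome order.
#' @export
genome_bounds <- function() {
  per_muscle <- rbind(gamma = c(0, 1), delta = c(0, 1),
                      mu1 = c(0, 2 * pi), mu2 = c(0, 2 * pi),
                      sigma1 = c(0.01, 2), sigma2 = c(0.01, 2))
  bounds <- do.call(rbind, replicate(10, per_muscle, simplify = FALSE))
  colnames(bounds) <- c("lower", "upper")
  bounds
}

#' GA configuration
#'
#' @param preset `"default"` (population 100, 300 generations) or `"smoke"`
#'   (24 x 30, a minutes-scale reduced search for testing).
#' @param population,generations,tournament,crossover_p,blend_alpha,
#'   mutation_p,mutation_sd_frac,elitism GA hyperparameters.
#' @param immigrants fraction of each generation replaced by fresh random
#'   genomes (diversity maintenance against premature convergence).
#' @param duration,dt candidate evaluation episode length and time step (s).
#' @param objective an [objective_config()].
#' @param kappa,theta_ref,cpg controller parameters, see [cpg_controller()].
#' @return list of class `ga_config`.
#' @export
ga_config <- function(preset = c("default", "smoke"), population = NULL,
                      generations = NULL, tournament = 3, crossover_p = 0.9,
                      blend_alpha = 0.5, mutation_p = 0.1,
                      mutation_sd_frac = 0.05, elitism = 2,
                      immigrants = 0.1, duration = 15,
                      dt = 1e-4, objective = objective_config(), kappa = 5,
                      theta_ref = 0.3, cpg = cpg_params()) {
  preset <- match.arg(preset)
  if (is.null(population)) population <- if (preset == "smoke") 24 else 100
  if (is.null(generations)) generations <- if (preset == "smoke") 30 else 300
  stopifnot(population >= 2)
  structure(list(population = population, generations = generations,
                 tournament = tournament, crossover_p = crossover_p,
                 blend_alpha = blend_alpha, mutation_p = mutation_p,
                 mutation_sd_frac = mutation_sd_frac, elitism = elitism,
                 immigrants = immigrants,
                 duration = duration, dt = dt, bounds = genome_bounds(),
                 objective = objective, kappa = kappa, theta_ref = theta_ref,
                 cpg = cpg), class = "ga_config")
}

#' Evaluate one genome
#'
#' Decodes the genome into muscle activation patterns, simulates a full
#' episode and scores it with [gait_objective()].  Out-of-bounds genes are
#' clamped to the bounds with a warning.  Deterministic for identical
#' inputs.
#'
#' @param genome numeric vector of length 60.
#' @param model an `msk_model`.
#' @param config a [ga_config()].
#' @param return_trial also return the simulated trial.
#' @return list with `J`, `terms`, `distance` and optionally `trial`.
#' @export
evaluate_candidate <- function(genome, model, config = ga_config(),
                               return_trial = FALSE) {
  stopifnot(length(genome) == 60)
  b <- config$bounds
  if (any(genome < b[, 1] | genome > b[, 2])) {
    warning("genome out of bounds; clamped")
    genome <- pmin(pmax(genome, b[, 1]), b[, 2])
  }
  ctrl <- cpg_controller(genome, cpg = config$cpg, kappa = config$kappa,
                         theta_ref = config$theta_ref)
  trial <- simulate_gait(model, ctrl, duration = config$duration,
                         dt = config$dt, record_dt = 2e-3,
                         on_nonfinite = "fall")
  obj <- gait_objective(trial, config$objective, cpg_T = config$cpg$T)
  out <- list(J = obj$J, terms = obj$terms, distance = trial$distance)
  if (return_trial) out$trial <- trial
  out
}

#' Random genome within bounds
#'
#' @param bounds from [genome_bounds()].
#' @return numeric vector of length 60 (uses the R RNG).
#' @export
random_genome <- function(bounds = genome_bounds()) {
  stats::runif(nrow(bounds), bounds[, 1], bounds[, 2])
}

#' Optimize muscle activation patterns with a real-coded GA
#'
#' Tournament selection, blend (BLX-alpha) crossover, per-gene Gaussian
#' mutation and elitism, minimizing the composite objective.  The staging of
#' the search (distance-first, then full shaping) emerges from the
#' objective's two regimes.  Fully driven by the R RNG: seed with
#' `set.seed()` or the `seed` argument for bitwise-reproducible runs.
#'
#' @param model an `msk_model`.
#' @param config a [ga_config()].
#' @param warm_start optional genome (or list of genomes) injected into the
#'   initial population, e.g. the previous solution in the heel-morphing
#'   schedule.
#' @param seed optional integer seed.
#' @param verbose print per-generation progress.
#' @return list with `best_genome`, `best_J`, `best_distance`, `history`
#'   (data.frame generation / best_J / mean_J / best_distance) and `config`.
#' @export
ga_optimize <- function(model, config = ga_config(), warm_start = NULL,
                        seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (config$population < 2) stop("population must be >= 2")
  b <- config$bounds
  npop <- config$population
  pop <- lapply(seq_len(npop), function(i) random_genome(b))
  if (!is.null(warm_start)) {
    ws <- if (is.list(warm_start)) warm_start else list(warm_start)
    for (i in seq_along(ws))
      pop[[i]] <- pmin(pmax(ws[[i]], b[, 1]), b[, 2])
  }
  evaluate <- function(g) evaluate_candidate(g, model, config)
  scores <- lapply(pop, evaluate)
  J <- vapply(scores, `[[`, 0, "J")
  dist <- vapply(scores, `[[`, 0, "distance")
  history <- data.frame(generation = 0, best_J = min(J), mean_J = mean(J),
                        best_distance = dist[which.min(J)])
  rng <- b[, 2] - b[, 1]
  for (gen in seq_len(config$generations)) {
    ord <- order(J)
    elite <- pop[ord[seq_len(config$elitism)]]
    eliteJ <- J[ord[seq_len(config$elitism)]]
    eliteD <- dist[ord[seq_len(config$elitism)]]
    tourn <- function() {
      k <- sample.int(npop, config$tournament)
      pop[[k[which.min(J[k])]]]
    }
    children <- list()
    while (length(children) < npop - config$elitism) {
      p1 <- tourn(); p2 <- tourn()
      if (stats::runif(1) < config$crossover_p) {
        lo <- pmin(p1, p2); hi <- pmax(p1, p2)
        d <- hi - lo
        c1 <- stats::runif(60, lo - config$blend_alpha * d,
                           hi + config$blend_alpha * d)
        c2 <- stats::runif(60, lo - config$blend_alpha * d,
                           hi + config$blend_alpha * d)
      } else { c1 <- p1; c2 <- p2 }
      for (ch in list(c1, c2)) {
        mut <- stats::runif(60) < config$mutation_p
        ch[mut] <- ch[mut] + stats::rnorm(sum(mut), 0,
                                          config$mutation_sd_frac * rng[mut])
        ch <- pmin(pmax(ch, b[, 1]), b[, 2])
        children[[length(children) + 1]] <- ch
      }
    }
    children <- children[seq_len(npop - config$elitism)]
    n_imm <- floor(config$immigrants * npop)
    if (n_imm > 0)
      for (k in seq_len(n_imm))
        children[[length(children) - k + 1]] <- random_genome(b)
    newscores <- lapply(children, evaluate)
    pop <- c(elite, children)
    J <- c(eliteJ, vapply(newscores, `[[`, 0, "J"))
    dist <- c(eliteD, vapply(newscores, `[[`, 0, "distance"))
    history <- rbind(history, data.frame(
      generation = gen, best_J = min(J), mean_J = mean(J),
      best_distance = dist[which.min(J)]))
    if (verbose)
      message(sprintf("gen %3d  best J %.3f  mean J %.1f  best D %.2f m",
                      gen, min(J), mean(J), dist[which.min(J)]))
  }
  best <- which.min(J)
  list(best_genome = pop[[best]], best_J = J[best],
       best_distance = dist[best], history = history, config = config)
}
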