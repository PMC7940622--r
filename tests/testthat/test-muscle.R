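test_that("PE force follows the printed exponential law", {
  m <- the_model
  expect_equal(pe_force(m, 0.15, 0.15), 0)
  # 10 mm stretch with the printed constants
  expect_equal(pe_force(m, 0.16, 0.15), 26 * (exp(1.5) - 1), tolerance = 1e-12)
  # compressive asymptote at -k1 when far below rest length
  expect_equal(pe_force(m, 0.05, 0.30), -26, tolerance = 1e-6)
  # optional non-negativity clamp
  p <- list(k1_pe = 26, k2_pe = 150, clamp_nonnegative = TRUE)
  expect_equal(pe_force(p, 0.05, 0.30), 0)
  expect_equal(pe_force(p, 0.16, 0.15), 26 * (exp(1.5) - 1))
})

test_that("total muscle force is F_max * a + f_pe with no F-L/F-V scaling", {
  sol <- the_model$muscles[[5]]
  expect_equal(sol$name, "SOL")
  f <- muscle_force(sol, 0.5, 10)
  expect_equal(f$total, 822 * 0.5 + 10)
  expect_equal(muscle_force(sol, 0, 0)$total, 0)
  expect_equal(muscle_force(sol, 1, 0)$total, 822)
  expect_error(muscle_force(sol, 1.2, 0), "activation")
  expect_error(muscle_force(sol, -0.1, 0), "activation")
})

test_that("muscle joint moments equal the virtual-work oracle", {
  m <- the_model
  set.seed(21)
  r <- m$joint_ranges
  h <- 1e-5
  for (rep in 1:8) {
    q <- c(hip = runif(1, r$hip[1], r$hip[2]),
           knee = runif(1, r$knee[1], r$knee[2]),
           ankle = runif(1, r$ankle[1], r$ankle[2]),
           mp = runif(1, r$mp[1], r$mp[2]))
    f <- runif(10, 0, 500)
    tau <- muscle_joint_moments(m, q, f)
    for (j in names(tau)) {
      qp <- q; qp[j] <- qp[j] + h
      qm <- q; qm[j] <- qm[j] - h
      dL <- vapply(macaquegait:::MUSCLE_NAMES, function(mn)
        (oracle_muscle_length(m, qp, mn) - oracle_muscle_length(m, qm, mn)) /
          (2 * h), numeric(1))
      expect_lt(abs(unname(tau[j]) - (-sum(f * dL))), 1e-7)
    }
  }
  expect_equal(unname(muscle_joint_moments(m, c(hip = 0.5), rep(0, 10))),
               rep(0, 4))
  # a single muscle with unit force produces its moment arm
  f1 <- c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0)
  q <- c(hip = 0.8, knee = -0.8, ankle = 1.0, mp = 0.3)
  expect_equal(unname(muscle_joint_moments(m, q, f1)["ankle"]),
               moment_arm(m, q, "SOL", "ankle"))
})

test_that("muscle power equals joint-moment power along a simulated trial", {
  # virtual-work consistency: sum_m f_m (-dL/dt) = sum_j tau_j thetadot_j,
  # with the fibre-velocity route taken through the independent complex
  # forward-kinematics oracle (directional finite difference)
  m <- the_model
  tr <- simulate_gait(m, cpg_controller(crafted_genome()), duration = 0.4,
                      record_dt = 1e-3,
                      options = macaquegait:::.sim_options(stop_on_fall = FALSE))
  h <- 1e-5
  for (i in seq(2, length(tr$time), by = 37)) {
    for (leg in c("R", "L")) {
      cols <- paste0(macaquegait:::MUSCLE_NAMES, "_", leg)
      qleg <- tr$q[i, paste0(macaquegait:::JOINT_NAMES, "_", leg)]
      names(qleg) <- macaquegait:::JOINT_NAMES
      qdleg <- tr$qd[i, paste0(macaquegait:::JOINT_NAMES, "_", leg, "_rate")]
      names(qdleg) <- macaquegait:::JOINT_NAMES
      f <- tr$f_total[i, cols]
      p_joint <- sum(muscle_joint_moments(m, qleg, f) * qdleg)
      ldot <- vapply(macaquegait:::MUSCLE_NAMES, function(mn) {
        cd <- function(hh)
          (oracle_muscle_length(m, qleg + hh * qdleg, mn) -
             oracle_muscle_length(m, qleg - hh * qdleg, mn)) / (2 * hh)
        (4 * cd(h / 2) - cd(h)) / 3   # Richardson-extrapolated central diff
      }, numeric(1))
      p_muscle <- sum(f * (-ldot))
      expect_lt(abs(p_joint - p_muscle), 1e-8 * max(1, abs(p_joint)))
    }
  }
})
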