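test_that("passive joint moments follow the viscous and knee-stop laws", {
  m <- the_model
  tau <- passive_joint_moments(m, c(knee = -0.23), c(knee = 0))
  expect_equal(unname(tau["knee"]), -1)            # exp(0) at the stop angle
  tau2 <- passive_joint_moments(m, c(knee = -0.33), c(knee = 0))
  expect_equal(unname(tau2["knee"]), -exp(-3), tolerance = 1e-12)
  tau3 <- passive_joint_moments(m, c(hip = 0), c(hip = 1))
  expect_equal(unname(tau3["hip"]), -0.109)
  tau4 <- passive_joint_moments(m, c(ankle = 0.5), c(ankle = -2))
  expect_equal(unname(tau4["ankle"]), 0.0943 * 2)
})

test_that("free passive chain conserves mechanical energy (< 0.1%/s)", {
  m <- the_model
  init <- default_init_state(m, forward_velocity = 0)
  opts <- macaquegait:::.sim_options(contact_on = FALSE, muscles_on = FALSE,
                                     passive_on = FALSE, stop_on_fall = FALSE)
  tr <- simulate_gait(m, fixed_controller(), duration = 1, dt = 1e-4,
                      record_dt = 0.05, init = init, options = opts)
  E <- vapply(seq_along(tr$time), function(i)
    mechanical_energy(m, tr$q[i, ], tr$qd[i, ])$total, numeric(1))
  drift <- abs(E[length(E)] - E[1]) / abs(E[1])
  expect_lt(drift, 0.001)
})

test_that("work-energy bookkeeping closes for a muscle-driven free chain", {
  # no ground, no viscosity: energy change equals total muscle fibre work
  m <- the_model
  init <- default_init_state(m, forward_velocity = 0)
  opts <- macaquegait:::.sim_options(contact_on = FALSE, passive_on = FALSE,
                                     stop_on_fall = FALSE)
  act <- rep(0.1, 20)
  tr <- simulate_gait(m, fixed_controller(act), duration = 0.3, dt = 1e-4,
                      record_dt = 1e-4, init = init, options = opts)
  E0 <- mechanical_energy(m, tr$q[1, ], tr$qd[1, ])$total
  E1 <- mechanical_energy(m, tr$q[nrow(tr$q), ], tr$qd[nrow(tr$q), ])$total
  n <- length(tr$time)
  ldot <- (tr$muscle_len[-1, ] - tr$muscle_len[-n, ]) / tr$dt
  fmid <- (tr$f_total[-1, ] + tr$f_total[-n, ]) / 2
  W <- -sum(fmid * ldot) * tr$dt
  expect_equal(E1 - E0, W, tolerance = 5e-3 * max(abs(W), 1))
})

test_that("stepping is deterministic and validates activations", {
  m <- the_model
  st <- default_init_state(m)
  a <- rep(0.3, 20)
  s1 <- step_dynamics(m, st, a, n = 50L)
  s2 <- step_dynamics(m, st, a, n = 50L)
  expect_identical(s1, s2)
  expect_error(step_dynamics(m, st, rep(1.5, 20)), "0, 1")
  expect_error(step_dynamics(m, st, rep(-0.1, 20)), "0, 1")
  # a state at rest without gravity stays at rest
  opts <- macaquegait:::.sim_options(gravity_on = FALSE, muscles_on = FALSE,
                                     passive_on = FALSE, contact_on = FALSE)
  st0 <- list(q = st$q, qd = rep(0, 11))
  s3 <- step_dynamics(m, st0, rep(0, 20), options = opts)
  expect_equal(s3$qd, rep(0, 11))
  expect_equal(s3$q, st0$q)
})

test_that("zero activation leads to a prompt fall with little travel", {
  m <- the_model
  tr <- simulate_gait(m, fixed_controller(), duration = 3)
  expect_true(tr$fell)
  expect_lt(tr$fall_time, 1.5)
  expect_lt(abs(tr$distance), 1)
})

test_that("trial recorder bookkeeping is consistent", {
  m <- the_model
  tr <- simulate_gait(m, cpg_controller(crafted_genome()), duration = 1,
                      record_dt = 1e-3,
                      options = macaquegait:::.sim_options(stop_on_fall = FALSE))
  n <- length(tr$time)
  expect_equal(n, floor(1 / 1e-3) + 1)
  for (f in c("q", "qd", "phases", "act", "f_total", "f_active", "f_pe",
              "muscle_len", "grf", "cop", "stance", "com", "vcom"))
    expect_equal(nrow(tr[[f]]), n, info = f)
  expect_true(all(is.finite(tr$q)))
  # active + pe components sum to the recorded total force
  expect_equal(tr$f_total, tr$f_active + tr$f_pe, tolerance = 1e-12)
  # COM matches the independent segment-mass-weighted oracle
  for (i in c(1, n %/% 2, n)) {
    bk <- body_kinematics(m, tr$q[i, ], tr$qd[i, ])
    expect_equal(unname(tr$com[i, ]),
                 c(sum(bk$mass * bk$com_x), sum(bk$mass * bk$com_y)) /
                   sum(bk$mass), tolerance = 1e-12)
  }
})

test_that("fall detection uses closed thresholds on height and pitch", {
  m <- the_model
  q0 <- default_init_state(m)$q
  h0 <- body_kinematics(m, q0)$com_y[1]
  expect_false(detect_fall(m, q0, h0))
  q_pitch <- q0; q_pitch[3] <- pi / 2
  expect_true(detect_fall(m, q_pitch, h0))       # boundary is closed
  q_low <- q0; q_low[2] <- q0[2] - 0.6 * h0
  expect_true(detect_fall(m, q_low, h0))
})
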