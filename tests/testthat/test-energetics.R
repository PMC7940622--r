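test_that("muscle work integrates contractile-element power", {
  # zero activations: no work either way
  tr <- make_fixture_gait(seed = 3)
  w <- muscle_work(tr, from_traces = TRUE)
  expect_true(all(w$W_pos == 0) && all(w$W_neg == 0))
  # constant 10 N active force shortening 0.01 m does 0.1 J of positive work
  tr2 <- tr
  n <- length(tr2$time)
  tr2$act[, "SOL_R"] <- 10 / tr2$f_max[["SOL_R"]]
  tr2$muscle_len[, "SOL_R"] <- seq(0.16, 0.15, length.out = n)
  w2 <- muscle_work(tr2, from_traces = TRUE)
  expect_equal(w2$W_pos[w2$muscle == "SOL_R"], 0.1, tolerance = 1e-6)
  expect_equal(w2$W_neg[w2$muscle == "SOL_R"], 0, tolerance = 1e-9)
  # symmetric lengthen-shorten cycle at constant activation: W+ = -W-
  tr3 <- tr
  tr3$act[, "VAS_L"] <- 0.2
  tr3$muscle_len[, "VAS_L"] <- 0.15 + 0.005 * sin(2 * pi * tr3$time)
  w3 <- muscle_work(tr3, from_traces = TRUE)
  i <- w3$muscle == "VAS_L"
  expect_equal(w3$W_pos[i], -w3$W_neg[i], tolerance = 1e-2)
  expect_gt(w3$W_pos[i], 0)
})

test_that("cost of transport follows the budget formula", {
  # no muscle work: basal power only
  tr <- make_fixture_gait(seed = 1, speed = 1.0, n_strides = 8)
  b <- energy_budget(tr, basal_rate = 20 / tr$total_mass)
  b$duration <- 10; b$distance <- 10; b$mass <- 10.038
  b$basal_power <- 20
  expect_equal(cost_of_transport(b), 200 / (10.038 * 10), tolerance = 1e-12)
  # doubling the distance at equal energy halves the COT
  b2 <- b; b2$distance <- 20
  expect_equal(cost_of_transport(b2), cost_of_transport(b) / 2)
  b3 <- b; b3$distance <- 0
  expect_error(cost_of_transport(b3), "distance")
  # efficiencies weight positive and negative work differently
  b4 <- b
  b4$work$W_pos[1] <- 1; b4$work$W_neg[2] <- -1.2
  expect_equal(cost_of_transport(b4),
               (1 / 0.25 + 1.2 / 1.2 + 200) / (10.038 * 10))
})

test_that("COM energies from the trial match direct formulas", {
  tr <- make_fixture_gait(seed = 2)
  ce <- com_energy(tr)
  M <- tr$total_mass
  expect_equal(ce$Ep, M * 9.81 * tr$com[, "com_y"])
  expect_equal(ce$Ek, 0.5 * M * (tr$vcom[, "vcom_x"]^2 +
                                   tr$vcom[, "vcom_y"]^2))
  expect_equal(ce$Eext, ce$Ep + ce$Ek)
  # static standing: constant Ep, zero Ek
  tr0 <- tr
  tr0$com[, "com_y"] <- 0.4; tr0$vcom[, ] <- 0
  ce0 <- com_energy(tr0)
  expect_equal(var(ce0$Ep), 0)
  expect_true(all(ce0$Ek == 0))
})

test_that("simulated COM trace equals the segment-mass-weighted oracle", {
  m <- the_model
  tr <- simulate_gait(m, cpg_controller(crafted_genome()), duration = 0.3,
                      record_dt = 5e-3,
                      options = macaquegait:::.sim_options(stop_on_fall = FALSE))
  for (i in c(1, 25, 61)) {
    bk <- body_kinematics(m, tr$q[i, ], tr$qd[i, ])
    expect_equal(unname(tr$com[i, "com_x"]),
                 sum(bk$mass * bk$com_x) / sum(bk$mass), tolerance = 1e-12)
    expect_equal(unname(tr$vcom[i, "vcom_y"]),
                 sum(bk$mass * bk$vcom_y) / sum(bk$mass), tolerance = 1e-12)
  }
})

test_that("percent recovery spans the pendular limits", {
  t <- seq(0, 4, by = 0.01)
  # perfect anti-phase, equal amplitude: 100%
  tr <- data.frame(Ep = cos(2 * pi * t), Ek = -cos(2 * pi * t))
  tr$Eext <- tr$Ep + tr$Ek
  expect_equal(percent_recovery(tr), 100)
  # in-phase: 0%
  tr2 <- data.frame(Ep = cos(2 * pi * t), Ek = 2 * cos(2 * pi * t))
  tr2$Eext <- tr2$Ep + tr2$Ek
  expect_equal(percent_recovery(tr2), 0)
  # flat energies: undefined
  tr3 <- data.frame(Ep = rep(1, 5), Ek = rep(2, 5), Eext = rep(3, 5))
  expect_true(is.na(percent_recovery(tr3)))
  # any random trace stays within [0, 100]
  set.seed(5)
  for (i in 1:10) {
    Ep <- cumsum(rnorm(200)); Ek <- cumsum(rnorm(200))
    tr4 <- data.frame(Ep = Ep, Ek = Ek, Eext = Ep + Ek)
    r <- percent_recovery(tr4)
    expect_gte(r, 0); expect_lte(r, 100)
  }
})

test_that("fixture recovery modes land in the intended regimes", {
  trp <- make_fixture_gait(seed = 4, recovery = "pendular")
  cep <- com_energy(trp)
  expect_gt(percent_recovery(cep), 90)
  tri <- make_fixture_gait(seed = 4, recovery = "inphase")
  cei <- com_energy(tri)
  expect_lt(percent_recovery(cei), 10)
})
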